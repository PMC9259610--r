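sample_id,group,d15N_alpha,d15N_beta,d18O
PE_01,PE,18.687657225855354,2.6303738614060865,64.42107507277882
PE_02,PE,16.92692581944929,-0.20879935592135368,68.57793017165562
PS_01,PS,23.12488229992441,2.9222423738789853,70.25458611132747
PS_02,PS,21.0480088546745,0.5113640909712256,68.74778585796263
PP_01,PP,20.66223121237897,-0.726992264774756,74.6136318700247
PP_02,PP,21.521637808968077,2.2537070337731215,72.61316352858395
PVC_01,PVC,23.135130324717547,-2.8368703912567845,77.68145130545005
PVC_02,PVC,18.855987175208657,-6.813393958662149,77.44745307425012
bulk_water_01,bulk_water,13.185299841042625,4.902099938522895,57.60713034152501
bulk_water_02,bulk_water,14.88031461409211,6.791451626706698,56.19026430634853
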