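id	name	group
1	visual	cortex_coarse32
2	auditory	cortex_coarse32
3	somatosensory	cortex_coarse32
4	precuneus	cortex_coarse32
5	posterior_cingulate	cortex_coarse32
6	frontal	cortex_coarse32
7	entorhinal	cortex_coarse32
8	sensory_thalamus	subcortex_coarse10
9	intralaminar_thalamus	subcortex_coarse10
10	hypothalamus	subcortex_coarse10
11	basal_forebrain	subcortex_coarse10
12	midbrain	subcortex_coarse10
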