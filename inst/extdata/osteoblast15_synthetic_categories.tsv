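set_name	category
OSTEOBLAST_DIFFERENTIATION_1	differentiation
OSTEOBLAST_DIFFERENTIATION_2	differentiation
OSTEOBLAST_DIFFERENTIATION_3	differentiation
OSTEOBLAST_DIFFERENTIATION_4	differentiation
OSTEOBLAST_DIFFERENTIATION_5	differentiation
OSTEOBLAST_DIFFERENTIATION_6	differentiation
OSTEOBLAST_DIFFERENTIATION_7	differentiation
OSTEOBLAST_DIFFERENTIATION_8	differentiation
OSTEOBLAST_DIFFERENTIATION_9	differentiation
OSTEOBLAST_TRANSCRIPTION_FACTOR_RUNX_LIKE	transcription_factor
OSTEOBLAST_DEVELOPMENT	development
OSTEOBLAST_PROLIFERATION_1	proliferation
OSTEOBLAST_PROLIFERATION_2	proliferation
OSTEOBLAST_PROLIFERATION_3	proliferation
OSTEOBLAST_SIGNALING	signaling
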