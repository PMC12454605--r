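outlet,Rp_Pa_s_per_mm3,C_mm3_per_Pa,Rd_Pa_s_per_mm3
left_subclavian,19.58,5.5e-4,286.2
left_common_carotid,44.70,3.23e-4,488.0
brachiocephalic_trunk,21.55,3.54e-4,443.2
distal_aorta,10.30,5.41e-4,443.2
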