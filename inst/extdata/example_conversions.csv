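conversion_id,form,a,b,input_metric,source_note
beetle_length_generic,power_law,0.0305,2.62,length,"illustrative generic beetle length (mm) to dry mass (mg) allometry"
copepod_length_loglog,log_log_linear,-7.62,2.85,length,"illustrative marine copepod prosome length (mm) to dry mass (mg), ln-ln form"
daphnia_volume,power_law,0.12,1.0,volume,"illustrative cladoceran body volume (mm^3) to dry mass (mg)"
insect_wet_fraction,dry_fraction,0.31,,wet_mass,"illustrative insect dry/wet mass fraction"
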