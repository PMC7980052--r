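# Denial phrases indicating the patient does not drink. One phrase per line.
non-drinker
nondrinker
non drinker
denies alcohol
denies etoh
denies drinking
denies any alcohol
no alcohol
no etoh
never drinks
never drank
never uses alcohol
does not drink
doesn't drink
teetotaller
teetotaler
abstains from alcohol
abstinent from alcohol
nil alcohol
zero alcohol
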