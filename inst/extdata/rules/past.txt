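# Phrases indicating past (former) alcohol use. One phrase per line.
# Matching is case-insensitive on normalized text, at word boundaries.
alcoholics anonymous
recovering
recovered
past
quit drinking
stopped drinking
former drinker
ex-drinker
sober since
in recovery
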