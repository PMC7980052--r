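# Markers for entries that mention alcohol without classifiable content:
# family history, unquantified or social use. Matching any of these only
# annotates the evidence; UNKNOWN is the fallback label regardless.
family history
father
mother
brother
sister
husband
wife
son
daughter
grandfather
grandmother
social drinker
drinks socially
socially
occasional
occasionally
sometimes
alcohol discussed
counselled re alcohol
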