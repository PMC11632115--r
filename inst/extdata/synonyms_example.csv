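variant,ingredient
mogamulizumab,mogamulizumab
MOGAMULIZUMAB,mogamulizumab
Mogamulizumab-kpkc,mogamulizumab
POTELIGEO,mogamulizumab
Poteligeo,mogamulizumab
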