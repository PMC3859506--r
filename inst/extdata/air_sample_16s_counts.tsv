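sample	n_sequences	n_chimeras
NY_INDOOR	410373	12503
NY_OUTDOOR	230506	5287
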