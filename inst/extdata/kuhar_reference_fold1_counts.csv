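optimizer,correct,total
gjo,5823,6225
warso,5860,6225
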