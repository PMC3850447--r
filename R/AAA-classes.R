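## Loaded first (collation order): S4 registration of ape's S3 tree class so
## that downstream classes can use "phylo" as a slot type.
methods::setOldClass("phylo")
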