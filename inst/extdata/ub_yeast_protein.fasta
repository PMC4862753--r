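>ubiquitin_yeast S. cerevisiae ubiquitin, 76 aa
MQIFVKTLTGKTITLEVESSDTIDNVKSKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG
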