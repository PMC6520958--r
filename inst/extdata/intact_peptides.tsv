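sequence	fraction
ATKPAN	Fr41
SGAASASGAA	Fr41
AGGPNQPPN	Fr42
AANITVPAAN	Fr42
EAEPAEAA	Fr43
GAAPTPPSPPPATKPSTPPKPPT	Fr43
PPNPPNPPN	Fr44
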