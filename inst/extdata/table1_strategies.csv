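setting,strategy,cost,utility
urban,FCG,1911.10,27.12
urban,POCT_HBA1C,1956.44,27.21
urban,VENOUS_HBA1C,2536.09,27.15
rural,FCG,2051.15,26.54
rural,POCT_HBA1C,2062.00,26.60
rural,VENOUS_HBA1C,2888.31,26.56
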