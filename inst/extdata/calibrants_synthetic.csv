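name,mass_da,charge,mz,ccs_lit_nm2
ubiquitin_n5,8565,5,1714.01,10.3
ubiquitin_n6,8565,6,1428.51,10.5
cytochrome_c_n6,12358,6,2060.67,12.4
cytochrome_c_n7,12358,7,1766.44,12.8
myoglobin_d9,16951,9,1884.45,26.0
myoglobin_d10,16951,10,1696.11,27.5
myoglobin_d11,16951,11,1542.01,29.0
myoglobin_d17,16951,17,998.13,41.0
myoglobin_d19,16951,19,893.17,44.5
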