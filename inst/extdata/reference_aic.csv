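year,null,exogenous,endogenous
2005,6031,6031,5432
2006,5637,5624,5004
2007,5240,5244,4782
2008,7856,7851,7355
2009,7763,7746,7277
2010,9289,9237,8808
2011,8729,8702,8276
2012,9560,9510,9053
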