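year,model,sigma,sigma_lo,sigma_hi,kappa_e4,kappa_lo,kappa_hi,mad_p
2005,exogenous,7.4,5.7,8.8,1.9,1.4,2.9,0.55
2006,exogenous,8.6,6.6,10.4,1.6,1.1,2.5,0.70
2007,exogenous,7.0,5.3,8.4,2.1,1.5,3.3,0.51
2008,exogenous,8.2,6.3,9.6,3.2,2.4,4.9,0.61
2009,exogenous,8.4,6.5,10.2,3.8,2.9,5.9,0.40
2010,exogenous,11.1,8.4,13.8,3.5,2.4,5.7,0.28
2011,exogenous,9.7,7.4,11.8,4.3,3.0,6.8,0.50
2012,exogenous,8.7,6.7,10.5,5.4,3.9,8.3,0.30
2005,endogenous,2.6,1.7,5.5,7.3,2.9,14.6,0.05
2006,endogenous,3.1,2.2,6.5,2.7,1.1,4.9,0.02
2007,endogenous,3.6,2.6,6.2,2.4,1.1,4.0,0.02
2008,endogenous,6.1,4.7,9.1,4.8,2.7,7.1,0.06
2009,endogenous,2.8,1.8,5.5,20.1,9.3,39.1,0.02
2010,endogenous,4.0,3.1,5.6,9.5,6.1,14.2,0.04
2011,endogenous,3.7,2.5,6.2,16.8,9.2,31.2,0.01
2012,endogenous,6.1,4.3,10.0,9.6,5.1,17.5,0.03
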