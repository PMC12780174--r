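type,i0,ssimSino,ssimSinoSd,psnrSino,psnrSinoSd,ssimRecon,ssimReconSd,psnrRecon,psnrReconSd
experimental,NA,0.2658,0.0963,19.8130,4.6583,0.1899,0.0987,21.8024,3.5996
simulated,200,0.2965,0.0409,25.7190,0.8567,0.1364,0.0307,21.4468,1.8307
simulated,250,0.3448,0.0435,26.6607,0.8634,0.1627,0.0356,22.3976,1.8311
simulated,300,0.3854,0.0451,27.4191,0.8678,0.1865,0.0397,23.1659,1.8317
simulated,350,0.4201,0.0459,28.0517,0.8725,0.2083,0.0432,23.8089,1.8325
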