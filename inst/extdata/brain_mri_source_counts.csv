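class,source,images
glioma,figshare,1426
glioma,SARTAJ,195
meningioma,figshare,708
meningioma,SARTAJ,937
pituitary,figshare,930
pituitary,SARTAJ,827
notumor,SARTAJ,500
notumor,Br35H,1500
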