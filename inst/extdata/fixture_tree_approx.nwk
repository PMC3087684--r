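(((((((((AUBUS001:1,AUPEA006:1):1,JPNAG062:1):1,L1:1):1,Tokyo1:1):1,(((((((HOY2:1,HOY3:1):1,MANL5:1):1,ONT5:1):1,ONT6:1):1,SAL4:1):1,SAL5:1):1,Russia:1):1):1,Littlefishpond2:1):1,((((((Bogoria1:1,MNCHU008:1):1,MNCHU024:1):1,Nakuru1:1):1,Nakuru2:1):1,OHJ1:1):1,OHJ4:1):1):1,(((((Mortlock5:1,(AUYEN020:1,Kordaclaypan56:1):1):1,Warrionlake37:1):1,((ALM7C29:1,Indianrocks1:1):1,Lostlake1:1):1):1,SM28:1):1,SM5:1):1):1,((Adriatic2:1,HONSS:1):1,Hawaii:1):1);
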