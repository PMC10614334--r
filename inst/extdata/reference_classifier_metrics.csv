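case,method,metric,value
valence,tri_ssu_bes,fdr,0.050877
valence,svm,fdr,0.34122
valence,tqwt,fdr,0.28333
valence,lstm,fdr,0.12371
valence,dbn,fdr,0.14041
valence,cnn,fdr,0.094488
valence,rnn,fdr,0.13433
valence,tri_ssu_bes,sensitivity,0.88399
valence,svm,sensitivity,0.63107
valence,tqwt,sensitivity,0.41748
valence,lstm,sensitivity,0.82524
valence,dbn,sensitivity,0.8123
valence,cnn,sensitivity,0.74434
valence,rnn,sensitivity,0.75081
valence,tri_ssu_bes,npv,0.95659
valence,svm,npv,0.69486
valence,tqwt,npv,0.84592
valence,lstm,npv,0.89124
valence,dbn,npv,0.87613
valence,cnn,npv,0.92749
valence,rnn,npv,0.89124
valence,tri_ssu_bes,specificity,0.95659
valence,svm,specificity,0.69486
valence,tqwt,specificity,0.84592
valence,lstm,specificity,0.89124
valence,dbn,specificity,0.87613
valence,cnn,specificity,0.92749
valence,rnn,specificity,0.89124
valence,tri_ssu_bes,fpr,0.043413
valence,svm,fpr,0.30514
valence,tqwt,fpr,0.15408
valence,lstm,fpr,0.10876
valence,dbn,fpr,0.12387
valence,cnn,fpr,0.072508
valence,rnn,fpr,0.10876
valence,tri_ssu_bes,f1,0.9154
valence,svm,f1,0.64463
valence,tqwt,f1,0.52761
valence,lstm,f1,0.85
valence,dbn,f1,0.83527
valence,cnn,f1,0.81705
valence,rnn,f1,0.80416
valence,tri_ssu_bes,for_,0.043413
valence,svm,for_,0.30514
valence,tqwt,for_,0.15408
valence,lstm,for_,0.10876
valence,dbn,for_,0.12387
valence,cnn,for_,0.072508
valence,rnn,for_,0.10876
valence,tri_ssu_bes,accuracy,0.92188
valence,svm,accuracy,0.66406
valence,tqwt,accuracy,0.63906
valence,lstm,accuracy,0.85938
valence,dbn,accuracy,0.84531
valence,cnn,accuracy,0.83906
valence,rnn,accuracy,0.82344
valence,tri_ssu_bes,mcc,0.84484
valence,svm,mcc,0.32666
valence,tqwt,mcc,0.29274
valence,lstm,mcc,0.71902
valence,dbn,mcc,0.69067
valence,cnn,mcc,0.68619
valence,rnn,mcc,0.65031
valence,tri_ssu_bes,precision,0.94912
valence,svm,precision,0.65878
valence,tqwt,precision,0.71667
valence,lstm,precision,0.87629
valence,dbn,precision,0.85959
valence,cnn,precision,0.90551
valence,rnn,precision,0.86567
valence,tri_ssu_bes,fnr,0.11601
valence,svm,fnr,0.36893
valence,tqwt,fnr,0.58252
valence,lstm,fnr,0.17476
valence,dbn,fnr,0.1877
valence,cnn,fnr,0.25566
valence,rnn,fnr,0.24919
arousal,tri_ssu_bes,sensitivity,0.93913
arousal,svm,sensitivity,0.74576
arousal,tqwt,sensitivity,0.5113
arousal,lstm,sensitivity,0.84463
arousal,dbn,sensitivity,0.82392
arousal,cnn,sensitivity,0.98305
arousal,rnn,sensitivity,0.83333
arousal,tri_ssu_bes,fdr,0.062229
arousal,svm,fdr,0.29223
arousal,tqwt,fdr,0.26423
arousal,lstm,fdr,0.17403
arousal,dbn,fdr,0.10469
arousal,cnn,fdr,0.30952
arousal,rnn,fdr,0.31395
arousal,tri_ssu_bes,precision,0.93777
arousal,svm,precision,0.70777
arousal,tqwt,precision,0.73577
arousal,lstm,precision,0.82597
arousal,dbn,precision,0.89531
arousal,cnn,precision,0.69048
arousal,rnn,precision,0.68605
arousal,tri_ssu_bes,fpr,0.072881
arousal,svm,fpr,0.38112
arousal,tqwt,fpr,0.22727
arousal,lstm,fpr,0.22028
arousal,dbn,fpr,0.11417
arousal,cnn,fpr,0.54545
arousal,rnn,fpr,0.47203
arousal,tri_ssu_bes,f1,0.93845
arousal,svm,f1,0.72627
arousal,tqwt,f1,0.60333
arousal,lstm,f1,0.8352
arousal,dbn,f1,0.85813
arousal,cnn,f1,0.81119
arousal,rnn,f1,0.75255
arousal,tri_ssu_bes,mcc,0.86636
arousal,svm,mcc,0.36766
arousal,tqwt,mcc,0.29029
arousal,lstm,mcc,0.62624
arousal,dbn,mcc,0.7072
arousal,cnn,mcc,0.53183
arousal,rnn,mcc,0.38257
arousal,tri_ssu_bes,fnr,0.06087
arousal,svm,fnr,0.25424
arousal,tqwt,fnr,0.4887
arousal,lstm,fnr,0.15537
arousal,dbn,fnr,0.17608
arousal,cnn,fnr,0.016949
arousal,rnn,fnr,0.16667
arousal,tri_ssu_bes,specificity,0.92712
arousal,svm,specificity,0.61888
arousal,tqwt,specificity,0.77273
arousal,lstm,specificity,0.77972
arousal,dbn,specificity,0.88583
arousal,cnn,specificity,0.45455
arousal,rnn,specificity,0.52797
arousal,tri_ssu_bes,npv,0.92712
arousal,svm,npv,0.61888
arousal,tqwt,npv,0.77273
arousal,lstm,npv,0.77972
arousal,dbn,npv,0.88583
arousal,cnn,npv,0.45455
arousal,rnn,npv,0.52797
arousal,tri_ssu_bes,accuracy,0.93359
arousal,svm,accuracy,0.68906
arousal,tqwt,accuracy,0.62813
arousal,lstm,accuracy,0.81563
arousal,dbn,accuracy,0.85225
arousal,cnn,accuracy,0.74687
arousal,rnn,accuracy,0.69688
arousal,tri_ssu_bes,for_,0.072881
arousal,svm,for_,0.38112
arousal,tqwt,for_,0.22727
arousal,lstm,for_,0.22028
arousal,dbn,for_,0.11417
arousal,cnn,for_,0.54545
arousal,rnn,for_,0.47203
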