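
     RDKit          3D

 65 68  0  0  0  0  0  0  0  0999 V2000
    3.3086   -3.2032   -2.3467 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0505   -1.7410   -2.6821 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2557   -1.0427   -1.5973 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8497   -1.1111   -1.6930 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0106   -0.5094   -0.7450 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3901   -0.5811   -0.8428 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2442    0.0156    0.1077 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7574   -0.1011   -0.0656 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2540   -1.5351   -0.3748 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.7462   -1.7055   -1.8095 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.8579   -0.7171   -2.1602 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.6971    0.6519   -1.4989 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2549    0.9323   -1.0947 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6570    0.7363    1.1696 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4590    1.4424    2.2429 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7907    0.5114    3.4106 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6227    1.2217    4.4664 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2514    0.7965    1.2671 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5883    0.1813    0.3254 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9909    0.2446    0.4289 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8492   -0.3654   -0.5048 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.3702   -0.2661   -0.3576 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9345    0.9373   -1.1347 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9280    2.2357   -0.3352 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.6938    2.0732    0.9702 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0985    0.9689    1.8317 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9367   -0.3538    1.0793 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3694   -3.7560   -2.2357 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8866   -3.6773   -3.1462 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8702   -3.3097   -1.4129 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5003   -1.6813   -3.6302 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.9947   -1.2221   -2.8751 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4027   -1.6485   -2.5283 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8205   -1.1162   -1.6859 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2305    0.1419    0.8922 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.0984   -1.7574    0.2927 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4922   -2.2888   -0.1436 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9110   -1.5683   -2.5055 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1070   -2.7290   -1.9624 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.8302   -1.1349   -1.8716 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.8907   -0.5996   -3.2501 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.0586    1.4327   -2.1777 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3344    0.6990   -0.6067 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1801    1.9413   -0.6708 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6243    0.9305   -1.9932 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3684    1.8790    1.8149 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8868    2.3034    2.6136 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3381   -0.3701    3.0572 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8658    0.1429    3.8708 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8420    0.5426    5.2962 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.5741    1.5658    4.0487 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0894    2.0887    4.8688 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1967    1.3386    2.0988 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4042    0.7948    1.2654 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.7713   -1.1669   -0.8384 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.9741    0.7126   -1.4093 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3957    1.0898   -2.0775 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8984    2.5514   -0.1314 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.3911    3.0307   -0.9313 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.7444    1.8429    0.7545 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6835    3.0180    1.5256 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.7414    0.8063    2.7054 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1392    1.3055    2.2339 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.9424   -0.7915    1.0018 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3534   -1.0573    1.6860 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  1  0
  8  9  1  0
  9 10  1  0
 10 11  1  0
 11 12  1  0
 12 13  1  0
  7 14  2  0
 14 15  1  0
 15 16  1  0
 16 17  1  0
 14 18  1  0
 18 19  2  0
 19 20  1  0
 20 21  2  0
 21 22  1  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 25 26  1  0
 26 27  1  0
 21  3  1  0
 27 22  1  0
 19  5  1  0
 13  8  1  0
  1 28  1  0
  1 29  1  0
  1 30  1  0
  2 31  1  0
  2 32  1  0
  4 33  1  0
  6 34  1  0
  8 35  1  0
  9 36  1  0
  9 37  1  0
 10 38  1  0
 10 39  1  0
 11 40  1  0
 11 41  1  0
 12 42  1  0
 12 43  1  0
 13 44  1  0
 13 45  1  0
 15 46  1  0
 15 47  1  0
 16 48  1  0
 16 49  1  0
 17 50  1  0
 17 51  1  0
 17 52  1  0
 18 53  1  0
 20 54  1  0
 22 55  1  0
 23 56  1  0
 23 57  1  0
 24 58  1  0
 24 59  1  0
 25 60  1  0
 25 61  1  0
 26 62  1  0
 26 63  1  0
 27 64  1  0
 27 65  1  0
M  END
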