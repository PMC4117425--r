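
     RDKit          3D

 18 19  0  0  0  0  0  0  0  0999 V2000
    2.2626    1.0772   -0.3600 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5185   -0.2538   -0.0437 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4595   -1.1256    0.2151 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1300   -0.6762    0.1607 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9470   -1.5400    0.4183 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2626   -1.0772    0.3600 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5185    0.2538    0.0437 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4595    1.1256   -0.2151 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1300    0.6762   -0.1607 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9470    1.5400   -0.4183 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0863    1.7568   -0.5616 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5424   -0.6153    0.0021 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6793   -2.1620    0.4606 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7669   -2.5833    0.6671 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0863   -1.7568    0.5616 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5424    0.6153   -0.0021 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6793    2.1620   -0.4606 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7669    2.5833   -0.6671 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10  1  1  0
  9  4  1  0
  1 11  1  0
  2 12  1  0
  3 13  1  0
  5 14  1  0
  6 15  1  0
  7 16  1  0
  8 17  1  0
 10 18  1  0
M  END
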