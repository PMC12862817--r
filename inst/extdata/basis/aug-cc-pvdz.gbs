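! aug-cc-pVDZ (standard published exponents/coefficients; Cartesian d).
****
H 0
S 4 1.00
     13.0100000              0.0196850
      1.9620000              0.1379770
      0.4446000              0.4781480
      0.1220000              0.5012400
S 1 1.00
      0.1220000              1.0000000
S 1 1.00
      0.0297400              1.0000000
P 1 1.00
      0.7270000              1.0000000
P 1 1.00
      0.1410000              1.0000000
****
O 0
S 9 1.00
  11720.0000000              0.0007100
   1759.0000000              0.0054700
    400.8000000              0.0278370
    113.7000000              0.1048000
     37.0300000              0.2830620
     13.2700000              0.4487190
      5.0250000              0.2709520
      1.0130000              0.0154580
      0.3023000             -0.0025850
S 9 1.00
  11720.0000000             -0.0001600
   1759.0000000             -0.0012630
    400.8000000             -0.0062670
    113.7000000             -0.0257160
     37.0300000             -0.0709240
     13.2700000             -0.1654110
      5.0250000             -0.1169550
      1.0130000              0.5573680
      0.3023000              0.5727590
S 1 1.00
      0.3023000              1.0000000
S 1 1.00
      0.0789600              1.0000000
P 3 1.00
     17.7000000              0.0430180
      3.8540000              0.2289130
      1.0460000              0.5087280
P 1 1.00
      0.2753000              1.0000000
P 1 1.00
      0.0685600              1.0000000
D 1 1.00
      1.1850000              1.0000000
D 1 1.00
      0.3320000              1.0000000
****
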