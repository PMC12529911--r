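# cc-pVTZ (Dunning). Spherical harmonics for d shells.
ELEMENT H
S 3
  33.8700000   0.0060680
  5.0950000    0.0453080
  1.1590000    0.2028220
S 1
  0.3258000    1.0000000
S 1
  0.1027000    1.0000000
P 1
  1.4070000    1.0000000
P 1
  0.3880000    1.0000000
D 1
  1.0570000    1.0000000
END
ELEMENT He
S 4
  234.0000000  0.0025870
  35.1600000   0.0195330
  7.9890000    0.0909980
  2.2120000    0.2720500
S 1
  0.6669000    1.0000000
S 1
  0.2089000    1.0000000
P 1
  3.0440000    1.0000000
P 1
  0.7580000    1.0000000
D 1
  1.9650000    1.0000000
END
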