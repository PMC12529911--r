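# cc-pVDZ (Dunning). Spherical d components are used when l = 2 appears.
ELEMENT H
S 4
  13.0100000   0.0196850
  1.9620000    0.1379770
  0.4446000    0.4781480
  0.1220000    0.5012400
S 1
  0.1220000    1.0000000
P 1
  0.7270000    1.0000000
END
ELEMENT He
S 3
  38.3600000   0.0238090
  5.7700000    0.1548910
  1.2400000    0.4699870
S 1
  0.2976000    1.0000000
P 1
  1.2750000    1.0000000
END
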