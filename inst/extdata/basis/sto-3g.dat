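# STO-3G minimal basis (Hehre, Stewart, Pople). Exponents/contraction
# coefficients for normalized primitives; SP shells stored as separate S and P
# shells sharing exponents.
ELEMENT H
S 3
  3.42525091   0.15432897
  0.62391373   0.53532814
  0.16885540   0.44463454
END
ELEMENT He
S 3
  6.36242139   0.15432897
  1.15892300   0.53532814
  0.31364979   0.44463454
END
ELEMENT Li
S 3
  16.11957475  0.15432897
  2.93620066   0.53532814
  0.79465050   0.44463454
S 3
  0.63628970  -0.09996723
  0.14786010   0.39951283
  0.04808870   0.70011547
P 3
  0.63628970   0.15591627
  0.14786010   0.60768372
  0.04808870   0.39195739
END
ELEMENT O
S 3
  130.70932000  0.15432897
  23.80886100   0.53532814
  6.44360830    0.44463454
S 3
  5.03315130   -0.09996723
  1.16959610    0.39951283
  0.38038900    0.70011547
P 3
  5.03315130    0.15591627
  1.16959610    0.60768372
  0.38038900    0.39195739
END
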