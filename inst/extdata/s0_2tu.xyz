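12
t=0 seed=0 preset=S0 synthetic=constructed-fixture
N       -0.76781800       1.08719200       0.00000000
C       -1.35190800      -0.14946200       0.00000000
N       -0.50380400      -1.22046400       0.00000000
C        0.86345100      -1.13607800       0.00000000
C        1.42481800       0.23055500       0.00000000
C        0.58842800       1.27163800       0.00000000
S       -2.99521177      -0.39425431       0.00000000
O        1.55687386      -2.14604596       0.00000000
H       -0.89916900      -2.14925300       0.00000000
H       -1.38764100       1.89217900       0.00000000
H        0.94188500       2.29777600       0.00000000
H        2.50151200       0.33002300       0.00000000
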