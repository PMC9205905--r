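# SYNTHETIC example assembly map for a pentacylindrical phycobilisome core.
# The chain IDs (c01..c90) are placeholders, NOT the chain naming of any
# deposited model: the true chain-to-cylinder correspondence of a deposition
# must be supplied by the user from the entry's own annotations. The role
# multiset matches the published subunit inventory of such a core:
# 38 ApcA, 40 ApcB, 6 ApcC, 2 ApcD, 2 ApcE (LCM), 2 ApcF.
# Cylinders: A, Aprime (3 APC trimers each), B (4), C, Cprime (2 each).

[chains]
c01 = A:1:ApcD:1
c02 = A:1:ApcB:1
c03 = A:1:ApcA:2
c04 = A:1:ApcB:2
c05 = A:1:ApcA:3
c06 = A:1:ApcB:3
c07 = A:2:ApcA:1
c08 = A:2:ApcB:1
c09 = A:2:ApcA:2
c10 = A:2:ApcB:2
c11 = A:2:ApcA:3
c12 = A:2:ApcB:3
c13 = A:3:ApcE:1
c14 = A:3:ApcF:1
c15 = A:3:ApcA:2
c16 = A:3:ApcB:2
c17 = A:3:ApcA:3
c18 = A:3:ApcB:3
c19 = Aprime:1:ApcD:1
c20 = Aprime:1:ApcB:1
c21 = Aprime:1:ApcA:2
c22 = Aprime:1:ApcB:2
c23 = Aprime:1:ApcA:3
c24 = Aprime:1:ApcB:3
c25 = Aprime:2:ApcA:1
c26 = Aprime:2:ApcB:1
c27 = Aprime:2:ApcA:2
c28 = Aprime:2:ApcB:2
c29 = Aprime:2:ApcA:3
c30 = Aprime:2:ApcB:3
c31 = Aprime:3:ApcE:1
c32 = Aprime:3:ApcF:1
c33 = Aprime:3:ApcA:2
c34 = Aprime:3:ApcB:2
c35 = Aprime:3:ApcA:3
c36 = Aprime:3:ApcB:3
c37 = B:1:ApcA:1
c38 = B:1:ApcB:1
c39 = B:1:ApcA:2
c40 = B:1:ApcB:2
c41 = B:1:ApcA:3
c42 = B:1:ApcB:3
c43 = B:2:ApcA:1
c44 = B:2:ApcB:1
c45 = B:2:ApcA:2
c46 = B:2:ApcB:2
c47 = B:2:ApcA:3
c48 = B:2:ApcB:3
c49 = B:3:ApcA:1
c50 = B:3:ApcB:1
c51 = B:3:ApcA:2
c52 = B:3:ApcB:2
c53 = B:3:ApcA:3
c54 = B:3:ApcB:3
c55 = B:4:ApcA:1
c56 = B:4:ApcB:1
c57 = B:4:ApcA:2
c58 = B:4:ApcB:2
c59 = B:4:ApcA:3
c60 = B:4:ApcB:3
c61 = C:1:ApcA:1
c62 = C:1:ApcB:1
c63 = C:1:ApcA:2
c64 = C:1:ApcB:2
c65 = C:1:ApcA:3
c66 = C:1:ApcB:3
c67 = C:2:ApcA:1
c68 = C:2:ApcB:1
c69 = C:2:ApcA:2
c70 = C:2:ApcB:2
c71 = C:2:ApcA:3
c72 = C:2:ApcB:3
c73 = Cprime:1:ApcA:1
c74 = Cprime:1:ApcB:1
c75 = Cprime:1:ApcA:2
c76 = Cprime:1:ApcB:2
c77 = Cprime:1:ApcA:3
c78 = Cprime:1:ApcB:3
c79 = Cprime:2:ApcA:1
c80 = Cprime:2:ApcB:1
c81 = Cprime:2:ApcA:2
c82 = Cprime:2:ApcB:2
c83 = Cprime:2:ApcA:3
c84 = Cprime:2:ApcB:3
c85 = B:1:ApcC:1
c86 = B:2:ApcC:1
c87 = C:1:ApcC:1
c88 = C:2:ApcC:1
c89 = Cprime:1:ApcC:1
c90 = Cprime:2:ApcC:1

[ligands]
codes = CYC

[dipole]
conjugated_atoms = NB C1B C2B C3B C4B CHB CHC NC C1C C2C C3C C4C CHD
sign_reference = CHB CHD
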