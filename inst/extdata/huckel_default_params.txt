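# Default Hueckel heteroatom parameters (classical Streitwieser-style table).
# Coulomb offsets h are in units of beta; resonance factors k are
# dimensionless scalings of beta.  Carbon defines the scale: h(C.pi) = 0 and
# k(C~C) = 1 exactly.
#
# Atom environments: .pi  = atom engaged in a multiple (or aromatic) bond,
#                    .lp  = lone-pair donor contributing two electrons,
#                    .vac = empty-p cation contributing zero electrons.
# Bond classes:      .single / .multiple (aromatic bonds between two .pi
#                    atoms count as multiple).

h C.pi     0
h C.lp     0
h C.vac    0
h B.pi    -0.45
h N.pi     0.5
h N.lp     1.5
h O.pi     1.0
h O.lp     2.0
h P.pi     0.2
h P.lp     0.8
h S.pi     0.4
h S.lp     1.3
h F.lp     3.0
h Cl.lp    2.0
h Br.lp    1.5
h I.lp     1.2

k C~C.single    1
k C~C.multiple  1
k B~C.single    0.7
k B~C.multiple  0.7
k C~N.single    0.8
k C~N.multiple  1.0
k C~O.single    0.8
k C~O.multiple  1.0
k N~N.single    0.8
k N~N.multiple  1.0
k N~O.single    0.8
k N~O.multiple  1.0
k O~O.single    0.8
k O~O.multiple  0.8
k C~S.single    0.6
k C~S.multiple  0.7
k C~P.single    0.7
k C~P.multiple  0.8
k N~S.single    0.6
k N~S.multiple  0.7
k C~F.single    0.7
k C~Cl.single   0.4
k C~Br.single   0.3
k C~I.single    0.25

# Optional affine map from the secular eigenvalue x to eV:
# E_eV = alpha + x * beta
ev alpha  -6.6
ev beta   -2.7
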