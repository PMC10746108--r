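# Example scheme extension: 1 mM cystamine solution plus a user-supplied
# hydroxyl scavenger with a single pseudo-first-order product.
solution:
  cystamine: 0.001
species:
  - name: TRIS
    charge: 0
    diffusion_coefficient: 0.8
    is_bulk: true
    conc: 0.0
    nH: 11
    nO: 3
    nN: 1
    nC: 4
  - name: TRISr
    charge: 0
    diffusion_coefficient: 0.8
    nH: 10
    nO: 3
    nN: 1
    nC: 4
reactions:
  - id: U1
    reactants: [OH, TRIS]
    products: [TRISr]
    k25: 1.1e9
    note: H abstraction; product carried as an inert organic radical
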