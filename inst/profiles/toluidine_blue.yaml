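name: toluidine_blue
description: Virtual toluidine blue (nuclei, stroma, metachromasia)
method: physical
background: [1.0, 1.0, 1.0]
floor: [0.0, 0.0, 0.0]
classes:
  - name: nuclei
    description: cell nuclei stained deep blue
    color: [0.24, 0.28, 0.68]
    scaling: 1.0
    markers: [dna1, dna2, dna, dapi, hoechst, histoneh3, h3, irdna, sytox]
  - name: stroma
    description: orthochromatic background tissue in light blue
    color: [0.65, 0.74, 0.90]
    scaling: 1.0
    markers: [vimentin, vim, col1a1, collagen, collagen1, fibronectin, fn1,
              asma, sma, desmin, actin]
  - name: metachromasia
    description: mast cell granules and glycosaminoglycans in purple-red
    color: [0.75, 0.40, 0.72]
    scaling: 1.0
    markers: [tryptase, tpsab1, chymase, cma1, cd117, kit, mcpt, heparin,
              aggrecan, acan, muc2]
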