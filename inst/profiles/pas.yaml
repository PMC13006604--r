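name: pas
description: Virtual periodic acid-Schiff (nuclei, polysaccharides, stroma)
method: physical
background: [1.0, 1.0, 1.0]
floor: [0.0, 0.0, 0.0]
classes:
  - name: nuclei
    description: cell nuclei counterstained blue by hematoxylin
    color: [0.32, 0.31, 0.66]
    scaling: 1.0
    markers: [dna1, dna2, dna, dapi, hoechst, histoneh3, h3, irdna, sytox]
  - name: polysaccharides
    description: glycogen, mucins and basement membranes stained magenta
    color: [0.82, 0.30, 0.58]
    scaling: 1.0
    markers: [muc1, muc2, muc5ac, mucin, wga, lectin, col4a1, collageniv,
              laminin, lamb1, glycogen]
  - name: stroma
    description: background stroma with light pink hue
    color: [0.95, 0.75, 0.82]
    scaling: 1.0
    markers: [vimentin, vim, col1a1, collagen, collagen1, fibronectin, fn1,
              asma, sma]
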