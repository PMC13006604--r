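name: jones_silver
description: Virtual Jones methenamine silver (membranes, stroma)
method: physical
background: [1.0, 1.0, 1.0]
floor: [0.0, 0.0, 0.0]
classes:
  - name: membranes
    description: basement membranes stained black by silver deposition
    color: [0.12, 0.12, 0.12]
    scaling: 1.0
    markers: [col4a1, collageniv, collagen4, laminin, lamb1, lamc1, nidogen,
              entactin, agrin]
  - name: stroma
    description: counterstained background tissue in light green
    color: [0.75, 0.87, 0.72]
    scaling: 1.0
    markers: [vimentin, vim, col1a1, collagen, collagen1, fibronectin, fn1,
              asma, sma, desmin]
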