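name: masson_trichrome
description: Virtual Masson trichrome (nuclei, muscle, collagen, erythrocytes)
method: physical
background: [1.0, 1.0, 1.0]
floor: [0.0, 0.0, 0.0]
classes:
  - name: nuclei
    description: cell nuclei stained dark blue-black
    color: [0.22, 0.22, 0.38]
    scaling: 1.0
    markers: [dna1, dna2, dna, dapi, hoechst, histoneh3, h3, irdna, sytox]
  - name: muscle
    description: muscle fibers and cytoplasm stained red
    color: [0.85, 0.35, 0.35]
    scaling: 1.0
    markers: [asma, sma, smoothmuscleactin, desmin, actin, myh11, myosin,
              troponin, mylk]
  - name: collagen
    description: collagen and connective tissue stained blue-green
    color: [0.38, 0.55, 0.82]
    scaling: 1.0
    markers: [col1a1, col3a1, collagen, collagen1, collagen3, collageni,
              collageniii, fibronectin, fn1, postn, periostin]
  - name: erythrocytes
    description: red blood cells
    color: [0.86, 0.33, 0.28]
    scaling: 1.0
    markers: [ter119, cd235a, glycophorina, gypa, hba, hbb, hemoglobin,
              haemoglobin]
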