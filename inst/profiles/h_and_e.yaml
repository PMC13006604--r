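# H&E stain profile: four classes driven by nuclear, stromal, epithelial and
# erythrocyte markers. Colors are transmission values in [0,1]; they are
# implementation defaults chosen to approximate routine H&E and can be edited
# freely. `palettes` holds alternative color sets emulating different
# microscope/scanner systems.
name: h_and_e
description: Virtual hematoxylin and eosin
method: physical
background: [1.0, 1.0, 1.0]
floor: [0.0, 0.0, 0.0]
classes:
  - name: nuclei
    description: cell nuclei stained blue-violet by hematoxylin
    color: [0.32, 0.31, 0.66]
    scaling: 1.0
    markers: [dna1, dna2, dna, dapi, hoechst, histoneh3, h3, irdna,
              propidiumiodide, drq5, nucleargreen, nuclearstain, sytox]
  - name: eosinophilic
    description: extracellular matrix and cytoplasm stained pink by eosin
    color: [0.95, 0.66, 0.75]
    scaling: 1.0
    markers: [col1a1, col3a1, collagen, collagen1, collagen3, collageni,
              collageniii, fibronectin, fn1, asma, sma, smoothmuscleactin,
              desmin, actin, laminin, vinculin, wga]
  - name: epithelial
    description: epithelial and other dense tissue stained purple
    color: [0.81, 0.57, 0.81]
    scaling: 1.0
    markers: [panck, pancytokeratin, pankeratin, cytokeratin, keratin, ck7,
              ck8, ck818, ck19, krt5, krt8, krt18, epcam, ecadherin, ecad,
              cdh1, vimentin, vim, cav1, caveolin, caveolin1, bcatenin]
  - name: erythrocytes
    description: red blood cells
    color: [0.84, 0.33, 0.28]
    scaling: 1.0
    markers: [ter119, cd235a, cd235ab, glycophorina, gypa, hba, hbb,
              hemoglobin, haemoglobin]
palettes:
  warm_scanner:
    nuclei: [0.38, 0.30, 0.62]
    eosinophilic: [0.97, 0.70, 0.78]
    epithelial: [0.85, 0.60, 0.80]
    erythrocytes: [0.88, 0.38, 0.30]
  cool_scanner:
    nuclei: [0.28, 0.30, 0.68]
    eosinophilic: [0.93, 0.64, 0.76]
    epithelial: [0.77, 0.55, 0.83]
    erythrocytes: [0.80, 0.30, 0.28]
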