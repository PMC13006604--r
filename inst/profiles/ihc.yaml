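# Generic IHC: hematoxylin counterstain plus a brown DAB chromogen for the
# target protein. The `target` marker list is intentionally empty: the user
# assigns the marker of interest manually or via the LLM route.
name: ihc
description: Virtual immunohistochemistry (hematoxylin + DAB)
method: physical
background: [1.0, 1.0, 1.0]
floor: [0.0, 0.0, 0.0]
classes:
  - name: nuclei
    description: cell nuclei counterstained blue by hematoxylin
    color: [0.32, 0.31, 0.66]
    scaling: 1.0
    markers: [dna1, dna2, dna, dapi, hoechst, histoneh3, h3, irdna,
              propidiumiodide, sytox]
  - name: target
    description: target protein visualized brown by DAB
    color: [0.65, 0.45, 0.22]
    scaling: 1.0
    markers: []
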