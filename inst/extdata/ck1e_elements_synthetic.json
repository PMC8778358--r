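{
  "comment": "Eight-element reference pharmacophore for the CK1e catalytic site. Element names, kinds and co-locations follow the published model; coordinates are SYNTHETIC stand-ins on the described triangular layout (hinge / buried / phosphate-region vertices) - the original geometry is not published.",
  "min_match": 6,
  "points": [
    { "name": "HBA",  "kind": "HBA", "x": 0.0,  "y": 0.0,  "z": 0.0, "radius": 1.0, "enabled": true, "group": null,        "provenance": "hinge backbone (Leu85), ligand acceptor" },
    { "name": "HBD1", "kind": "HBD", "x": 1.8,  "y": 0.6,  "z": 0.0, "radius": 1.0, "enabled": true, "group": null,        "provenance": "hinge backbone (Leu85), ligand donor" },
    { "name": "HBD2", "kind": "HBD", "x": 3.5,  "y": 2.0,  "z": 1.0, "radius": 1.0, "enabled": true, "group": null,        "provenance": "Glu83 backbone, ligand donor" },
    { "name": "Aro1", "kind": "Aro", "x": -2.0, "y": 5.5,  "z": 1.5, "radius": 1.0, "enabled": true, "group": "Aro1/Hyd1", "provenance": "Phe20 ring stacking" },
    { "name": "Hyd1", "kind": "Hyd", "x": -2.0, "y": 5.5,  "z": 1.5, "radius": 1.0, "enabled": true, "group": "Aro1/Hyd1", "provenance": "Phe20 hydrophobic, co-located with Aro1" },
    { "name": "Hyd2", "kind": "Hyd", "x": 2.5,  "y": -4.5, "z": 0.5, "radius": 1.0, "enabled": true, "group": "Hyd2/Aro2", "provenance": "buried pocket (Ala36/Pro66/Met82/Leu135/Ile148), merged" },
    { "name": "Aro2", "kind": "Aro", "x": 2.5,  "y": -4.5, "z": 0.5, "radius": 1.0, "enabled": true, "group": "Hyd2/Aro2", "provenance": "ring bridging the hydrogen-bond elements, co-located with Hyd2" },
    { "name": "Hyd3", "kind": "Hyd", "x": 5.0,  "y": -2.5, "z": 2.0, "radius": 1.0, "enabled": true, "group": null,        "provenance": "Lys38 aliphatic side chain" }
  ]
}
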