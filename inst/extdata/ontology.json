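{
  "version": "1.0",
  "provenance": "reconstructed",
  "units": [
    {"name": "mm", "dim": "length", "factor": 1},
    {"name": "cm", "dim": "length", "factor": 10},
    {"name": "count", "dim": "count", "factor": 1}
  ],
  "structures": [
    {"name": "plant", "parent": null, "synonyms": [], "note": "whole plant"},
    {"name": "stem", "parent": "plant", "synonyms": [], "note": ""},
    {"name": "internode", "parent": "stem", "synonyms": [], "note": "distinct stem internodes"},
    {"name": "leaf", "parent": "plant", "synonyms": [], "note": ""},
    {"name": "basal-leaf", "parent": "plant", "synonyms": [], "note": "rosulate leaves on the lowermost stem"},
    {"name": "cauline-leaf", "parent": "stem", "synonyms": [], "note": "stem leaves above the rosette"},
    {"name": "inflorescence", "parent": "plant", "synonyms": ["dichasium"], "note": "terminal compound dichasium"},
    {"name": "branch", "parent": "inflorescence", "synonyms": [], "note": ""},
    {"name": "flower", "parent": "inflorescence", "synonyms": [], "note": ""},
    {"name": "pedicel", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "calyx", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "tooth", "parent": "calyx", "synonyms": ["calyx-tooth"], "note": "calyx teeth, heteromorphic: three longer and two shorter"},
    {"name": "petal", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "claw", "parent": "petal", "synonyms": [], "note": "lower part of the petal"},
    {"name": "limb", "parent": "petal", "synonyms": [], "note": "upper part of the petal"},
    {"name": "lobe", "parent": "limb", "synonyms": [], "note": ""},
    {"name": "coronal-scale", "parent": "petal", "synonyms": [], "note": "scales at the junction of claw and limb"},
    {"name": "anthophore", "parent": "flower", "synonyms": [], "note": "structure separating the attachment of calyx and corolla"},
    {"name": "anther", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "filament", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "style", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "capsule", "parent": "flower", "synonyms": [], "note": ""},
    {"name": "seed", "parent": "capsule", "synonyms": [], "note": ""},
    {"name": "testa", "parent": "seed", "synonyms": [], "note": "seed coat"}
  ],
  "properties": [
    {"name": "length", "kind": "quantitative", "canonical_unit": "mm"},
    {"name": "width", "kind": "quantitative", "canonical_unit": "mm"},
    {"name": "height", "kind": "quantitative", "canonical_unit": "mm"},
    {"name": "number", "kind": "count"},
    {"name": "relative-length", "kind": "relative"},
    {"name": "life-form", "kind": "qualitative", "states": ["annual", "perennial"]},
    {"name": "habit", "kind": "qualitative", "states": ["erect", "spreading", "ascending"]},
    {"name": "shape", "kind": "qualitative",
     "states": ["linear", "lanceolate", "oblanceolate", "spathulate", "ovate",
                "obovate", "elliptic", "oblong", "deltoid", "ellipsoid",
                "ovoid", "reniform", "cylindrical", "clavate", "campanulate",
                "triangular"]},
    {"name": "indumentum", "kind": "qualitative",
     "states": ["glabrous", "puberulent", "densely-puberulent",
                "sparsely-pubescent", "pubescent", "tomentose",
                "densely-tomentose", "villous", "scabrous", "papillate",
                "ciliate", "sessile-glands"]},
    {"name": "apex", "kind": "qualitative",
     "states": ["entire", "emarginate", "dentate", "erose", "laciniate",
                "crenate", "mucronate", "acuminate", "acute"]},
    {"name": "apex-orientation", "kind": "qualitative",
     "states": ["geniculate", "antrorse", "erect"],
     "applicable_structures": ["pedicel"]},
    {"name": "color", "kind": "qualitative",
     "states": ["white", "pink", "pale-pink", "carmine", "green", "reddish",
                "purple"]},
    {"name": "flowering-time", "kind": "qualitative",
     "states": ["diurnal", "nocturnal"], "applicable_structures": ["flower"]},
    {"name": "cleft", "kind": "qualitative",
     "states": ["less-than-middle", "middle-or-more"],
     "applicable_structures": ["limb"]},
    {"name": "division", "kind": "qualitative",
     "states": ["entire", "emarginate", "bifid", "divided"],
     "applicable_structures": ["limb"]},
    {"name": "margin-width", "kind": "qualitative",
     "states": ["narrow", "broad"], "applicable_structures": ["tooth"]},
    {"name": "marginal-hair-length", "kind": "qualitative",
     "states": ["short", "long"], "applicable_structures": ["tooth"]},
    {"name": "marginal-hair-density", "kind": "qualitative",
     "states": ["sparse", "dense"], "applicable_structures": ["tooth"]},
    {"name": "divarication", "kind": "qualitative",
     "states": ["divaricate", "non-divaricate"],
     "applicable_structures": ["inflorescence"]},
    {"name": "position", "kind": "qualitative",
     "states": ["exserted", "slightly-exserted", "included"],
     "applicable_structures": ["anther", "style"]},
    {"name": "texture", "kind": "qualitative",
     "states": ["fleshy", "smooth", "papillate", "fragile", "robust"]},
    {"name": "translucency", "kind": "qualitative",
     "states": ["opaque", "translucent"],
     "applicable_structures": ["capsule"]},
    {"name": "arrangement", "kind": "qualitative",
     "states": ["divergent", "curled"], "applicable_structures": ["lobe"]}
  ],
  "specifiers": [
    {"base_structure": "internode", "discriminator": "position",
     "declared": true, "allowed_values": ["uppermost", "next-upper"]},
    {"base_structure": "flower", "discriminator": "order",
     "declared": true, "allowed_values": ["first"]},
    {"base_structure": "tooth", "discriminator": "class",
     "declared": true, "allowed_values": ["shorter", "longer"]}
  ],
  "modifiers": {
    "frequency": ["usually", "sometimes", "rarely", "often", "mostly"],
    "temporal": ["at-anthesis", "in-fruit", "in-flower"],
    "spatial": ["upper-surface", "lower-surface", "in-lower-part",
                "in-upper-part", "throughout", "at-apex"],
    "relative": ["less-than", "equal-to", "more-than"]
  }
}
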