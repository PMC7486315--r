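{
  "name": "silene-arenosae",
  "slots": [
    {"structure": "plant", "property": "life-form", "label": ""},
    {"structure": "plant", "property": "height", "label": "", "suffix": "tall"},
    {"structure": "plant", "property": "habit", "label": ""},
    {"structure": "stem", "property": "indumentum", "label": "Stem"},
    {"structure": "internode", "property": "number", "label": "distinct internodes"},
    {"structure": "internode[position=uppermost]", "property": "length",
     "label": "the uppermost internode", "suffix": "long", "sentence": false},
    {"structure": "internode[position=uppermost]", "property": "relative-length",
     "label": "the uppermost internode", "sentence": false},
    {"structure": "basal-leaf", "property": "shape", "label": "Basal leaves"},
    {"structure": "basal-leaf", "property": "length", "label": "Basal leaves"},
    {"structure": "basal-leaf", "property": "width", "label": "Basal leaves"},
    {"structure": "basal-leaf", "property": "indumentum", "label": "Basal leaves"},
    {"structure": "leaf", "property": "texture", "label": "Leaves"},
    {"structure": "cauline-leaf", "property": "shape", "label": "Cauline leaves"},
    {"structure": "cauline-leaf", "property": "length", "label": "Cauline leaves"},
    {"structure": "cauline-leaf", "property": "width", "label": "Cauline leaves"},
    {"structure": "cauline-leaf", "property": "indumentum", "label": "Cauline leaves"},
    {"structure": "calyx", "property": "length", "label": "Calyx", "suffix": "long"},
    {"structure": "calyx", "property": "shape", "label": "Calyx"},
    {"structure": "calyx", "property": "indumentum", "label": "Calyx"},
    {"structure": "tooth[class=shorter]", "property": "length",
     "label": "shorter ones", "sentence": false},
    {"structure": "tooth[class=shorter]", "property": "shape",
     "label": "shorter ones", "sentence": false},
    {"structure": "tooth[class=shorter]", "property": "apex",
     "label": "shorter ones", "sentence": false},
    {"structure": "tooth[class=longer]", "property": "length",
     "label": "longer ones", "sentence": false},
    {"structure": "tooth[class=longer]", "property": "shape",
     "label": "longer ones", "sentence": false},
    {"structure": "tooth[class=longer]", "property": "apex",
     "label": "longer ones", "sentence": false},
    {"structure": "tooth[class=shorter]", "property": "margin-width",
     "label": "shorter-teeth margin", "sentence": false},
    {"structure": "tooth[class=longer]", "property": "margin-width",
     "label": "longer-teeth margin", "sentence": false},
    {"structure": "tooth", "property": "marginal-hair-length",
     "label": "marginal hairs", "sentence": false},
    {"structure": "tooth", "property": "marginal-hair-density",
     "label": "marginal hairs", "sentence": false},
    {"structure": "flower", "property": "flowering-time", "label": "Flowers"},
    {"structure": "inflorescence", "property": "divarication",
     "label": "Inflorescence"},
    {"structure": "claw", "property": "length", "label": "Petal claws",
     "suffix": "long"},
    {"structure": "claw", "property": "indumentum", "label": "Petal claws"},
    {"structure": "limb", "property": "length", "label": "limbs",
     "suffix": "long", "sentence": false},
    {"structure": "limb", "property": "division", "label": "limbs",
     "sentence": false},
    {"structure": "limb", "property": "color", "label": "limbs",
     "sentence": false},
    {"structure": "limb", "property": "cleft", "label": "limbs",
     "sentence": false},
    {"structure": "lobe", "property": "shape", "label": "lobes",
     "sentence": false},
    {"structure": "lobe", "property": "arrangement", "label": "lobes",
     "sentence": false},
    {"structure": "coronal-scale", "property": "length",
     "label": "coronal scales", "suffix": "long", "sentence": false},
    {"structure": "coronal-scale", "property": "shape",
     "label": "coronal scales", "sentence": false},
    {"structure": "coronal-scale", "property": "apex",
     "label": "coronal scales", "sentence": false},
    {"structure": "anthophore", "property": "length", "label": "Anthophore",
     "suffix": "long"},
    {"structure": "anthophore", "property": "indumentum",
     "label": "Anthophore"},
    {"structure": "anther", "property": "position", "label": "Anthers"},
    {"structure": "filament", "property": "length", "label": "filaments",
     "suffix": "long", "sentence": false},
    {"structure": "filament", "property": "indumentum", "label": "filaments",
     "sentence": false},
    {"structure": "style", "property": "number", "label": "Styles"},
    {"structure": "style", "property": "position", "label": "Styles"},
    {"structure": "flower[order=first]/pedicel", "property": "length",
     "label": "First pedicel"},
    {"structure": "flower[order=first]/pedicel", "property": "habit",
     "label": "First pedicel"},
    {"structure": "flower[order=first]/pedicel", "property": "indumentum",
     "label": "First pedicel"},
    {"structure": "flower[order=first]/pedicel", "property": "apex-orientation",
     "label": "First pedicel"},
    {"structure": "capsule", "property": "length", "label": "Capsule",
     "suffix": "long"},
    {"structure": "capsule", "property": "shape", "label": "Capsule"},
    {"structure": "capsule", "property": "texture", "label": "Capsule"},
    {"structure": "capsule", "property": "translucency", "label": "Capsule"},
    {"structure": "seed", "property": "width", "label": "Seeds",
     "suffix": "wide"},
    {"structure": "seed", "property": "height", "label": "Seeds",
     "suffix": "high"},
    {"structure": "seed", "property": "shape", "label": "Seeds"},
    {"structure": "testa", "property": "texture", "label": "testa",
     "sentence": false}
  ]
}
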