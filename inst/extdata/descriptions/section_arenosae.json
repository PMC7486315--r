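{
  "taxon": "Silene sect. Arenosae",
  "rank": "section",
  "template": "silene-arenosae",
  "elements": [
    {
      "structure": "plant",
      "property": "life-form",
      "score": {
        "type": "states",
        "states": [
          "annual"
        ]
      }
    },
    {
      "structure": "plant",
      "property": "height",
      "score": {
        "type": "range",
        "main_low": 5,
        "main_high": 70,
        "unit": "cm"
      }
    },
    {
      "structure": "plant",
      "property": "habit",
      "score": {
        "type": "states",
        "states": [
          "ascending",
          "erect"
        ]
      }
    },
    {
      "structure": "cauline-leaf",
      "property": "shape",
      "score": {
        "type": "states",
        "states": [
          "lanceolate",
          "linear",
          "oblanceolate"
        ]
      }
    },
    {
      "structure": "tooth[class=shorter]",
      "property": "margin-width",
      "score": {
        "type": "states",
        "states": [
          "broad"
        ]
      }
    },
    {
      "structure": "tooth",
      "property": "marginal-hair-density",
      "score": {
        "type": "states",
        "states": [
          "dense"
        ]
      },
      "modifiers": [
        {
          "kind": "frequency",
          "value": "usually"
        }
      ]
    },
    {
      "structure": "flower",
      "property": "flowering-time",
      "score": {
        "type": "states",
        "states": [
          "nocturnal"
        ]
      },
      "modifiers": [
        {
          "kind": "frequency",
          "value": "usually"
        }
      ]
    },
    {
      "structure": "style",
      "property": "number",
      "score": {
        "type": "count",
        "main_low": 3,
        "main_high": 3
      }
    },
    {
      "structure": "capsule",
      "property": "shape",
      "score": {
        "type": "states",
        "states": [
          "ellipsoid",
          "oblong",
          "obovate"
        ]
      }
    },
    {
      "structure": "seed",
      "property": "shape",
      "score": {
        "type": "states",
        "states": [
          "reniform"
        ]
      }
    }
  ]
}
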