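{
  "dairy_servings": 3,
  "plans": [
    {
      "name": "model1",
      "components": [
        {
          "ref": "composite:A",
          "servings": 3
        }
      ]
    },
    {
      "name": "model2",
      "components": [
        {
          "ref": "composite:A",
          "servings": 2
        },
        {
          "ref": "composite:B",
          "servings": 1
        }
      ]
    },
    {
      "name": "model3",
      "components": [
        {
          "ref": "composite:A",
          "servings": 2
        },
        {
          "ref": "composite:C",
          "servings": 1
        }
      ]
    },
    {
      "name": "model4",
      "components": [
        {
          "ref": "composite:A",
          "servings": 2
        },
        {
          "ref": "food:11111000",
          "servings": 1
        }
      ]
    },
    {
      "name": "model5",
      "components": [
        {
          "ref": "composite:A",
          "servings": 2
        },
        {
          "ref": "food:11112110",
          "servings": 1
        }
      ]
    },
    {
      "name": "model6",
      "components": [
        {
          "ref": "composite:A",
          "servings": 2
        },
        {
          "ref": "food:14410110",
          "servings": 1
        }
      ]
    },
    {
      "name": "model7",
      "components": [
        {
          "ref": "composite:A",
          "servings": 2
        },
        {
          "ref": "food:14410120",
          "servings": 1
        }
      ]
    }
  ]
}
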