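{
  "format": "clocknet-model",
  "version": 1,
  "entities": [
    {
      "name": "X",
      "max_level": 1
    },
    {
      "name": "Y",
      "max_level": 1
    }
  ],
  "interactions": [
    {
      "source": "X",
      "target": "Y",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "Y",
      "target": "X",
      "sign": "-",
      "threshold": 1
    }
  ],
  "parameters": {
    "X{}": 0,
    "X{Y}": 1,
    "Y{}": 0,
    "Y{X}": 1
  }
}
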