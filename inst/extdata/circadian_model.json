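{
  "format": "clocknet-model",
  "version": 1,
  "entities": [
    {
      "name": "Bmal",
      "max_level": 1
    },
    {
      "name": "CB",
      "max_level": 1
    },
    {
      "name": "PC",
      "max_level": 1
    },
    {
      "name": "Rev",
      "max_level": 1
    },
    {
      "name": "Myc",
      "max_level": 1
    },
    {
      "name": "p53",
      "max_level": 1
    }
  ],
  "interactions": [
    {
      "source": "Bmal",
      "target": "CB",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "CB",
      "target": "PC",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "CB",
      "target": "Rev",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "Bmal",
      "target": "p53",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "Myc",
      "target": "p53",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "Myc",
      "target": "Myc",
      "sign": "+",
      "threshold": 1
    },
    {
      "source": "PC",
      "target": "CB",
      "sign": "-",
      "threshold": 1
    },
    {
      "source": "Rev",
      "target": "Bmal",
      "sign": "-",
      "threshold": 1
    },
    {
      "source": "CB",
      "target": "Myc",
      "sign": "-",
      "threshold": 1
    },
    {
      "source": "p53",
      "target": "Myc",
      "sign": "-",
      "threshold": 1
    }
  ],
  "parameter_space": {
    "Bmal{}": 0,
    "Bmal{Rev}": 1,
    "CB{}": 0,
    "CB{Bmal,PC}": 1,
    "CB{Bmal}": [0, 1],
    "CB{PC}": 0,
    "Myc{}": 0,
    "Myc{CB,Myc,p53}": 1,
    "Myc{CB,Myc}": 0,
    "Myc{CB,p53}": [0, 1],
    "Myc{CB}": 0,
    "Myc{Myc,p53}": 0,
    "Myc{Myc}": [0, 1],
    "Myc{p53}": 0,
    "p53{}": 0,
    "p53{Bmal,Myc}": 1,
    "p53{Bmal}": 1,
    "p53{Myc}": 1,
    "PC{}": 0,
    "PC{CB}": 1,
    "Rev{}": 0,
    "Rev{CB}": 1
  },
  "parameters": {
    "Bmal{}": 0,
    "Bmal{Rev}": 1,
    "CB{}": 0,
    "CB{Bmal,PC}": 1,
    "CB{Bmal}": 1,
    "CB{PC}": 0,
    "Myc{}": 0,
    "Myc{CB,Myc,p53}": 1,
    "Myc{CB,Myc}": 0,
    "Myc{CB,p53}": 1,
    "Myc{CB}": 0,
    "Myc{Myc,p53}": 0,
    "Myc{Myc}": 0,
    "Myc{p53}": 0,
    "p53{}": 0,
    "p53{Bmal,Myc}": 1,
    "p53{Bmal}": 1,
    "p53{Myc}": 1,
    "PC{}": 0,
    "PC{CB}": 1,
    "Rev{}": 0,
    "Rev{CB}": 1
  },
  "rate_presets": {
    "normal": [
      {
        "entity": "Bmal",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "CB",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "PC",
        "activation": 0.97,
        "inhibition": 1
      },
      {
        "entity": "Rev",
        "activation": 0.97,
        "inhibition": 1
      },
      {
        "entity": "Myc",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "p53",
        "activation": 1,
        "inhibition": 1
      }
    ],
    "mild": [
      {
        "entity": "Bmal",
        "activation": 0.5,
        "inhibition": 1.3
      },
      {
        "entity": "CB",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "PC",
        "activation": 0.4,
        "inhibition": 1.3
      },
      {
        "entity": "Rev",
        "activation": 0.4,
        "inhibition": 1
      },
      {
        "entity": "Myc",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "p53",
        "activation": 1,
        "inhibition": 1
      }
    ],
    "chronic": [
      {
        "entity": "Bmal",
        "activation": 0.15,
        "inhibition": 2
      },
      {
        "entity": "CB",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "PC",
        "activation": 0.2,
        "inhibition": 2
      },
      {
        "entity": "Rev",
        "activation": 0.2,
        "inhibition": 1
      },
      {
        "entity": "Myc",
        "activation": 1,
        "inhibition": 1
      },
      {
        "entity": "p53",
        "activation": 1,
        "inhibition": 1
      }
    ]
  },
  "gate_schedule": [
    {
      "entity": "Bmal",
      "on": 18,
      "off": 6
    },
    {
      "entity": "Rev",
      "on": 0,
      "off": 8
    },
    {
      "entity": "PC",
      "on": 6,
      "off": 18
    }
  ]
}
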