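{
  "components": [
    {
      "name": "DSBs_early",
      "max_level": 1,
      "default_level": 0,
      "annotation": "-P = phosphorylation"
    },
    {
      "name": "DSBs_late",
      "max_level": 1,
      "default_level": 0,
      "annotation": "-P = phosphorylation"
    },
    {
      "name": "RPA-ATR-ATRIP-P",
      "max_level": 1,
      "default_level": 0,
      "annotation": "-P = phosphorylation"
    },
    {
      "name": "ATM-P",
      "max_level": 1,
      "default_level": 0,
      "annotation": "-P = phosphorylation"
    },
    {
      "name": "p53-P",
      "max_level": 1,
      "default_level": 0,
      "annotation": "-P = phosphorylation"
    },
    {
      "name": "nuclear_p50-p65-P",
      "max_level": 1,
      "default_level": 0,
      "annotation": "-P = phosphorylation"
    }
  ],
  "terms": [
    {
      "id": 1,
      "target": "DSBs_late",
      "target_level": 1,
      "time_scale": 2,
      "literals": [
        {
          "component": "DSBs_early",
          "negated": false,
          "threshold": 1
        }
      ]
    },
    {
      "id": 2,
      "target": "RPA-ATR-ATRIP-P",
      "target_level": 1,
      "time_scale": 1,
      "literals": [
        {
          "component": "DSBs_late",
          "negated": false,
          "threshold": 1
        }
      ]
    },
    {
      "id": 3,
      "target": "ATM-P",
      "target_level": 1,
      "time_scale": 1,
      "literals": [
        {
          "component": "DSBs_early",
          "negated": false,
          "threshold": 1
        },
        {
          "component": "p53-P",
          "negated": true,
          "threshold": 1
        }
      ]
    },
    {
      "id": 4,
      "target": "p53-P",
      "target_level": 1,
      "time_scale": 1,
      "literals": [
        {
          "component": "ATM-P",
          "negated": false,
          "threshold": 1
        },
        {
          "component": "p53-P",
          "negated": true,
          "threshold": 1
        }
      ]
    },
    {
      "id": 5,
      "target": "p53-P",
      "target_level": 1,
      "time_scale": 1,
      "literals": [
        {
          "component": "p53-P",
          "negated": true,
          "threshold": 1
        },
        {
          "component": "RPA-ATR-ATRIP-P",
          "negated": false,
          "threshold": 1
        }
      ]
    },
    {
      "id": 6,
      "target": "nuclear_p50-p65-P",
      "target_level": 1,
      "time_scale": 1,
      "literals": [
        {
          "component": "ATM-P",
          "negated": false,
          "threshold": 1
        },
        {
          "component": "nuclear_p50-p65-P",
          "negated": true,
          "threshold": 1
        }
      ]
    }
  ],
  "outputs": []
}
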