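{
  "provenance": "Generated programmatically by the naive exhaustive reference implementation (tests/testthat/helper-oracle.R); regenerate with scripts/regenerate_toy_suite.R. Do not hand-edit.",
  "networks": [
    {
      "name": "unconnected2",
      "gates": [
        {
          "inputs": [],
          "table": "0"
        },
        {
          "inputs": [],
          "table": "0"
        }
      ],
      "state": [0, 0],
      "phi_mechanisms": [
        {
          "mechanism": "1",
          "phi": 0
        },
        {
          "mechanism": "2",
          "phi": 0
        },
        {
          "mechanism": "1,2",
          "phi": 0
        }
      ],
      "big_phi": 0,
      "main_complex": {
        "nodes": [1, 2],
        "phi": 0
      }
    },
    {
      "name": "selfcopy",
      "gates": [
        {
          "inputs": 1,
          "table": "01"
        }
      ],
      "state": 1,
      "phi_mechanisms": [
        {
          "mechanism": "1",
          "phi": 0.5
        }
      ],
      "big_phi": 0.5,
      "main_complex": {
        "nodes": 1,
        "phi": 0.5
      }
    },
    {
      "name": "copyloop2",
      "gates": [
        {
          "inputs": 2,
          "table": "01"
        },
        {
          "inputs": 1,
          "table": "01"
        }
      ],
      "state": [1, 1],
      "phi_mechanisms": [
        {
          "mechanism": "1",
          "phi": 0.5
        },
        {
          "mechanism": "2",
          "phi": 0.5
        },
        {
          "mechanism": "1,2",
          "phi": 0
        }
      ],
      "big_phi": 1,
      "main_complex": {
        "nodes": [1, 2],
        "phi": 1
      }
    },
    {
      "name": "and_loop3",
      "gates": [
        {
          "inputs": [2, 3],
          "table": "0001"
        },
        {
          "inputs": 1,
          "table": "01"
        },
        {
          "inputs": 2,
          "table": "01"
        }
      ],
      "state": [1, 1, 1],
      "phi_mechanisms": [
        {
          "mechanism": "1",
          "phi": 0.5
        },
        {
          "mechanism": "2",
          "phi": 0.5
        },
        {
          "mechanism": "1,2",
          "phi": 0
        },
        {
          "mechanism": "3",
          "phi": 0.25
        },
        {
          "mechanism": "1,3",
          "phi": 0
        },
        {
          "mechanism": "2,3",
          "phi": 0
        },
        {
          "mechanism": "1,2,3",
          "phi": 0
        }
      ],
      "big_phi": 0.4375,
      "main_complex": {
        "nodes": [1, 2],
        "phi": 1
      }
    }
  ]
}
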