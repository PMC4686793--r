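{
  "tapes": 2,
  "ordered": true,
  "start": "S",
  "stop": "ee",
  "symbols": [
    {
      "name": "S",
      "role": "start",
      "boundary": "empty"
    },
    {
      "name": "ee",
      "role": "stop",
      "boundary": "empty",
      "consumes": [0, 0]
    },
    {
      "name": "M",
      "role": "nonterminal",
      "boundary": "empty"
    },
    {
      "name": "D",
      "role": "nonterminal",
      "boundary": "empty"
    },
    {
      "name": "I",
      "role": "nonterminal",
      "boundary": "empty"
    },
    {
      "name": "uv",
      "role": "terminal",
      "boundary": "empty",
      "consumes": [1, 1]
    },
    {
      "name": "u-",
      "role": "terminal",
      "boundary": "empty",
      "consumes": [1, 0]
    },
    {
      "name": "u.",
      "role": "terminal",
      "boundary": "empty",
      "consumes": [1, 0]
    },
    {
      "name": "-v",
      "role": "terminal",
      "boundary": "empty",
      "consumes": [0, 1]
    },
    {
      "name": ".v",
      "role": "terminal",
      "boundary": "empty",
      "consumes": [0, 1]
    }
  ],
  "productions": [
    {
      "lhs": "S",
      "rhs": [
        "M"
      ],
      "attribute": "start_m"
    },
    {
      "lhs": "S",
      "rhs": [
        "D"
      ],
      "attribute": "start_d"
    },
    {
      "lhs": "S",
      "rhs": [
        "I"
      ],
      "attribute": "start_i"
    },
    {
      "lhs": "M",
      "rhs": [
        "M",
        "uv"
      ],
      "attribute": "subst_mm"
    },
    {
      "lhs": "M",
      "rhs": [
        "D",
        "uv"
      ],
      "attribute": "subst_dm"
    },
    {
      "lhs": "M",
      "rhs": [
        "I",
        "uv"
      ],
      "attribute": "subst_im"
    },
    {
      "lhs": "M",
      "rhs": [
        "ee"
      ],
      "attribute": "empty_m"
    },
    {
      "lhs": "D",
      "rhs": [
        "M",
        "u-"
      ],
      "attribute": "open_md"
    },
    {
      "lhs": "D",
      "rhs": [
        "D",
        "u."
      ],
      "attribute": "extend_dd"
    },
    {
      "lhs": "D",
      "rhs": [
        "I",
        "u-"
      ],
      "attribute": "open_id"
    },
    {
      "lhs": "D",
      "rhs": [
        "ee"
      ],
      "attribute": "empty_d"
    },
    {
      "lhs": "I",
      "rhs": [
        "M",
        "-v"
      ],
      "attribute": "open_mi"
    },
    {
      "lhs": "I",
      "rhs": [
        "D",
        "-v"
      ],
      "attribute": "open_di"
    },
    {
      "lhs": "I",
      "rhs": [
        "I",
        ".v"
      ],
      "attribute": "extend_ii"
    },
    {
      "lhs": "I",
      "rhs": [
        "ee"
      ],
      "attribute": "empty_i"
    }
  ]
}
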