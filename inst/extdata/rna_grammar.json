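{
  "tapes": 1,
  "ordered": true,
  "start": "S",
  "stop": "eps",
  "symbols": [
    {
      "name": "S",
      "role": "start",
      "boundary": "empty"
    },
    {
      "name": "eps",
      "role": "stop",
      "boundary": "empty",
      "consumes": 0
    },
    {
      "name": "U",
      "role": "nonterminal",
      "boundary": "empty"
    },
    {
      "name": "B",
      "role": "nonterminal",
      "boundary": "point-pair"
    },
    {
      "name": "c",
      "role": "terminal",
      "boundary": "empty",
      "consumes": 1
    },
    {
      "name": "c'",
      "role": "terminal",
      "boundary": "empty",
      "consumes": 1
    }
  ],
  "productions": [
    {
      "lhs": "S",
      "rhs": [
        "U"
      ],
      "attribute": "start"
    },
    {
      "lhs": "U",
      "rhs": [
        "c",
        "U"
      ],
      "attribute": "unpaired"
    },
    {
      "lhs": "U",
      "rhs": [
        "B",
        "U"
      ],
      "attribute": "paired_prefix"
    },
    {
      "lhs": "U",
      "rhs": [
        "eps"
      ],
      "attribute": "empty"
    },
    {
      "lhs": "B",
      "rhs": [
        "c",
        "U",
        "c'"
      ],
      "attribute": "pair"
    }
  ]
}
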