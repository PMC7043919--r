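[
  {
    "name": "0_1",
    "determinant": 1,
    "alexander": [
      1
    ]
  },
  {
    "name": "3_1",
    "determinant": 3,
    "alexander": [
      1,
      -1,
      1
    ]
  },
  {
    "name": "4_1",
    "determinant": 5,
    "alexander": [
      -1,
      3,
      -1
    ]
  },
  {
    "name": "5_1",
    "determinant": 5,
    "alexander": [
      1,
      -1,
      1,
      -1,
      1
    ]
  },
  {
    "name": "5_2",
    "determinant": 7,
    "alexander": [
      2,
      -3,
      2
    ]
  },
  {
    "name": "6_1",
    "determinant": 9,
    "alexander": [
      -2,
      5,
      -2
    ]
  },
  {
    "name": "6_2",
    "determinant": 11,
    "alexander": [
      -1,
      3,
      -3,
      3,
      -1
    ]
  },
  {
    "name": "6_3",
    "determinant": 13,
    "alexander": [
      1,
      -3,
      5,
      -3,
      1
    ]
  },
  {
    "name": "7_1",
    "determinant": 7,
    "alexander": [
      1,
      -1,
      1,
      -1,
      1,
      -1,
      1
    ]
  },
  {
    "name": "7_2",
    "determinant": 11,
    "alexander": [
      3,
      -5,
      3
    ]
  },
  {
    "name": "7_3",
    "determinant": 13,
    "alexander": [
      2,
      -3,
      3,
      -3,
      2
    ]
  },
  {
    "name": "7_4",
    "determinant": 15,
    "alexander": [
      4,
      -7,
      4
    ]
  },
  {
    "name": "7_5",
    "determinant": 17,
    "alexander": [
      2,
      -4,
      5,
      -4,
      2
    ]
  },
  {
    "name": "7_6",
    "determinant": 19,
    "alexander": [
      -1,
      5,
      -7,
      5,
      -1
    ]
  },
  {
    "name": "7_7",
    "determinant": 21,
    "alexander": [
      1,
      -5,
      9,
      -5,
      1
    ]
  },
  {
    "name": "8_1",
    "determinant": 13,
    "alexander": [
      -3,
      7,
      -3
    ]
  },
  {
    "name": "8_2",
    "determinant": 17,
    "alexander": [
      -1,
      3,
      -3,
      3,
      -3,
      3,
      -1
    ]
  },
  {
    "name": "8_3",
    "determinant": 17,
    "alexander": [
      -4,
      9,
      -4
    ]
  },
  {
    "name": "8_4",
    "determinant": 19,
    "alexander": [
      -2,
      5,
      -5,
      5,
      -2
    ]
  },
  {
    "name": "8_5",
    "determinant": 21,
    "alexander": [
      -1,
      3,
      -4,
      5,
      -4,
      3,
      -1
    ]
  },
  {
    "name": "8_6",
    "determinant": 23,
    "alexander": [
      -2,
      6,
      -7,
      6,
      -2
    ]
  },
  {
    "name": "8_7",
    "determinant": 23,
    "alexander": [
      1,
      -3,
      5,
      -5,
      5,
      -3,
      1
    ]
  },
  {
    "name": "8_8",
    "determinant": 25,
    "alexander": [
      2,
      -6,
      9,
      -6,
      2
    ]
  },
  {
    "name": "8_9",
    "determinant": 25,
    "alexander": [
      -1,
      3,
      -5,
      7,
      -5,
      3,
      -1
    ]
  },
  {
    "name": "8_10",
    "determinant": 27,
    "alexander": [
      1,
      -3,
      6,
      -7,
      6,
      -3,
      1
    ]
  },
  {
    "name": "8_11",
    "determinant": 27,
    "alexander": [
      -2,
      7,
      -9,
      7,
      -2
    ]
  },
  {
    "name": "8_12",
    "determinant": 29,
    "alexander": [
      1,
      -7,
      13,
      -7,
      1
    ]
  },
  {
    "name": "8_13",
    "determinant": 29,
    "alexander": [
      2,
      -7,
      11,
      -7,
      2
    ]
  },
  {
    "name": "8_14",
    "determinant": 31,
    "alexander": [
      -2,
      8,
      -11,
      8,
      -2
    ]
  },
  {
    "name": "8_15",
    "determinant": 33,
    "alexander": [
      3,
      -8,
      11,
      -8,
      3
    ]
  },
  {
    "name": "8_16",
    "determinant": 35,
    "alexander": [
      1,
      -4,
      8,
      -9,
      8,
      -4,
      1
    ]
  },
  {
    "name": "8_17",
    "determinant": 37,
    "alexander": [
      -1,
      4,
      -8,
      11,
      -8,
      4,
      -1
    ]
  },
  {
    "name": "8_18",
    "determinant": 45,
    "alexander": [
      -1,
      5,
      -10,
      13,
      -10,
      5,
      -1
    ]
  },
  {
    "name": "8_19",
    "determinant": 3,
    "alexander": [
      1,
      -1,
      0,
      1,
      0,
      -1,
      1
    ]
  },
  {
    "name": "8_20",
    "determinant": 9,
    "alexander": [
      1,
      -2,
      3,
      -2,
      1
    ],
    "jones": [
      "t^-1:-1,2,-1,2,-1,1,-1"
    ]
  },
  {
    "name": "8_21",
    "determinant": 15,
    "alexander": [
      -1,
      4,
      -5,
      4,
      -1
    ]
  },
  {
    "name": "3_1#3_1",
    "determinant": 9,
    "alexander": [
      1,
      -2,
      3,
      -2,
      1
    ],
    "jones": [
      "t^-8:1,-2,1,-2,2,0,1",
      "t^-3:-1,1,-1,3,-1,1,-1"
    ]
  }
]
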