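graph
[
  node
  [
    id 1
    value 1
  ]
  node
  [
    id 2
    value 1
  ]
  node
  [
    id 3
    value 1
  ]
  node
  [
    id 4
    value 1
  ]
  node
  [
    id 5
    value 1
  ]
  node
  [
    id 6
    value 1
  ]
  node
  [
    id 7
    value 1
  ]
  node
  [
    id 8
    value 1
  ]
  node
  [
    id 9
    value 1
  ]
  node
  [
    id 10
    value 2
  ]
  node
  [
    id 11
    value 1
  ]
  node
  [
    id 12
    value 1
  ]
  node
  [
    id 13
    value 1
  ]
  node
  [
    id 14
    value 1
  ]
  node
  [
    id 15
    value 2
  ]
  node
  [
    id 16
    value 2
  ]
  node
  [
    id 17
    value 1
  ]
  node
  [
    id 18
    value 1
  ]
  node
  [
    id 19
    value 2
  ]
  node
  [
    id 20
    value 1
  ]
  node
  [
    id 21
    value 2
  ]
  node
  [
    id 22
    value 1
  ]
  node
  [
    id 23
    value 2
  ]
  node
  [
    id 24
    value 2
  ]
  node
  [
    id 25
    value 2
  ]
  node
  [
    id 26
    value 2
  ]
  node
  [
    id 27
    value 2
  ]
  node
  [
    id 28
    value 2
  ]
  node
  [
    id 29
    value 2
  ]
  node
  [
    id 30
    value 2
  ]
  node
  [
    id 31
    value 2
  ]
  node
  [
    id 32
    value 2
  ]
  node
  [
    id 33
    value 2
  ]
  node
  [
    id 34
    value 2
  ]
  edge
  [
    source 1
    target 2
  ]
  edge
  [
    source 1
    target 3
  ]
  edge
  [
    source 1
    target 4
  ]
  edge
  [
    source 1
    target 5
  ]
  edge
  [
    source 1
    target 6
  ]
  edge
  [
    source 1
    target 7
  ]
  edge
  [
    source 1
    target 8
  ]
  edge
  [
    source 1
    target 9
  ]
  edge
  [
    source 1
    target 11
  ]
  edge
  [
    source 1
    target 12
  ]
  edge
  [
    source 1
    target 13
  ]
  edge
  [
    source 1
    target 14
  ]
  edge
  [
    source 1
    target 18
  ]
  edge
  [
    source 1
    target 20
  ]
  edge
  [
    source 1
    target 22
  ]
  edge
  [
    source 1
    target 32
  ]
  edge
  [
    source 2
    target 3
  ]
  edge
  [
    source 2
    target 4
  ]
  edge
  [
    source 2
    target 8
  ]
  edge
  [
    source 2
    target 14
  ]
  edge
  [
    source 2
    target 18
  ]
  edge
  [
    source 2
    target 20
  ]
  edge
  [
    source 2
    target 22
  ]
  edge
  [
    source 2
    target 31
  ]
  edge
  [
    source 3
    target 4
  ]
  edge
  [
    source 3
    target 8
  ]
  edge
  [
    source 3
    target 9
  ]
  edge
  [
    source 3
    target 10
  ]
  edge
  [
    source 3
    target 14
  ]
  edge
  [
    source 3
    target 28
  ]
  edge
  [
    source 3
    target 29
  ]
  edge
  [
    source 3
    target 33
  ]
  edge
  [
    source 4
    target 8
  ]
  edge
  [
    source 4
    target 13
  ]
  edge
  [
    source 4
    target 14
  ]
  edge
  [
    source 5
    target 7
  ]
  edge
  [
    source 5
    target 11
  ]
  edge
  [
    source 6
    target 7
  ]
  edge
  [
    source 6
    target 11
  ]
  edge
  [
    source 6
    target 17
  ]
  edge
  [
    source 7
    target 17
  ]
  edge
  [
    source 9
    target 31
  ]
  edge
  [
    source 9
    target 33
  ]
  edge
  [
    source 9
    target 34
  ]
  edge
  [
    source 10
    target 34
  ]
  edge
  [
    source 14
    target 34
  ]
  edge
  [
    source 15
    target 33
  ]
  edge
  [
    source 15
    target 34
  ]
  edge
  [
    source 16
    target 33
  ]
  edge
  [
    source 16
    target 34
  ]
  edge
  [
    source 19
    target 33
  ]
  edge
  [
    source 19
    target 34
  ]
  edge
  [
    source 20
    target 34
  ]
  edge
  [
    source 21
    target 33
  ]
  edge
  [
    source 21
    target 34
  ]
  edge
  [
    source 23
    target 33
  ]
  edge
  [
    source 23
    target 34
  ]
  edge
  [
    source 24
    target 26
  ]
  edge
  [
    source 24
    target 28
  ]
  edge
  [
    source 24
    target 30
  ]
  edge
  [
    source 24
    target 33
  ]
  edge
  [
    source 24
    target 34
  ]
  edge
  [
    source 25
    target 26
  ]
  edge
  [
    source 25
    target 28
  ]
  edge
  [
    source 25
    target 32
  ]
  edge
  [
    source 26
    target 32
  ]
  edge
  [
    source 27
    target 30
  ]
  edge
  [
    source 27
    target 34
  ]
  edge
  [
    source 28
    target 34
  ]
  edge
  [
    source 29
    target 32
  ]
  edge
  [
    source 29
    target 34
  ]
  edge
  [
    source 30
    target 33
  ]
  edge
  [
    source 30
    target 34
  ]
  edge
  [
    source 31
    target 33
  ]
  edge
  [
    source 31
    target 34
  ]
  edge
  [
    source 32
    target 33
  ]
  edge
  [
    source 32
    target 34
  ]
  edge
  [
    source 33
    target 34
  ]
]
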