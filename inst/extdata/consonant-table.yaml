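consonants:
  p:
    place: labial
    manner: stop
  b:
    place: labial
    manner: stop
  m:
    place: labial
    manner: nasal
  t:
    place: coronal
    manner: stop
  d:
    place: coronal
    manner: stop
  'n':
    place: coronal
    manner: nasal
  k:
    place: dorsal
    manner: stop
  g:
    place: dorsal
    manner: stop
vowels:
- a
- i
- u
- e
- o
- ɑ
- æ
- ɛ
- ɪ
- ʊ
- ə
- ʌ
- ɔ
frontness:
  i: front
  e: front
  ɪ: front
  ɛ: front
  æ: front
  a: center
  ə: center
  ʌ: center
  u: back
  o: back
  ʊ: back
  ɔ: back
  ɑ: back
aliases:
  ん: 'n'
  ン: 'n'
  ɴ: 'n'
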