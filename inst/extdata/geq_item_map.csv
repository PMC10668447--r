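item,factor
1,positive_affect
2,competence
3,flow
4,negativity
5,positive_affect
6,competence
7,flow
8,negativity
9,positive_affect
10,competence
11,flow
12,negativity
13,positive_affect
14,competence
15,flow
16,negativity
17,positive_affect
18,competence
19,flow
20,negativity
21,positive_affect
22,competence
23,flow
24,negativity
25,positive_affect
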