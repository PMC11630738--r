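# SWC reconstruction
1 1 0 0 0 8 -1
2 3 -8.08609927 13.7017221 -16.7394236 1 1
3 3 4.96720401 7.20124089 27.2035117 1 1
4 3 -12.717281 20.2785431 -33.9894809 0.5 2
5 3 12.5215615 6.34968321 41.6896928 0.5 3
6 3 -21.1635586 32.1447186 -46.8092385 0.333333333 4
7 3 -7.78681591 29.3537671 -64.6931935 0.333333333 4
8 3 23.2516669 -0.474700303 58.2001394 0.333333333 5
9 3 -32.5496796 51.9038508 -53.5856449 0.3 6
10 3 -11.5396181 38.2841902 -84.4620694 0.3 7
11 3 26.8666833 -5.03646859 69.0564482 0.3 8
12 3 -50.3926948 67.5806396 -63.2675167 0.3 9
13 3 -17.9663789 48.5873198 -101.140941 0.3 10
14 3 33.0961498 -11.0424964 83.1769431 0.3 11
15 3 33.9478852 -14.4296469 81.3241031 0.3 11
16 3 -61.5491819 79.3209367 -76.1455783 0.3 12
17 3 -22.5262126 64.7109951 -111.586188 0.3 13
18 3 43.2687366 -9.72198677 110.580693 0.3 14
19 3 51.6517529 -29.9995171 91.192376 0.3 15
20 3 38.0895636 -27.4663801 92.1478105 0.3 15
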