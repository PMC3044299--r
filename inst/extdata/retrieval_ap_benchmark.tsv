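initial	added	proposed	pubmed
1c4z	1fxt	0.76	0.64
1c4z	1fbv	0.78	0.68
1c4z	1ayz	0.68	0.73
1c4z	1y8q	0.78	0.53
1c4z	1nd7	0.78	0.53
1c4z	1u9a	0.69	0.82
1c4z	1kps	0.77	0.60
2uyz	1tgz	0.68	0.55
2uyz	2iy0	0.69	0.60
2uyz	1y8r	0.81	0.65
2uyz	2nvu	0.65	0.57
2uyz	2eke	0.66	0.92
2uyz	1wyw	0.76	0.58
2uyz	2asq	0.72	0.52
1fxt	1c4z	0.76	0.64
1fxt	1j7d	0.72	0.57
1fxt	1vcb	0.83	0.74
1fxt	1s1q	0.58	0.53
1fxt	1euv	0.63	0.51
1fxt	1fqv	0.79	0.78
1ldk	1p22	1.00	0.91
1ldk	2hye	0.77	0.81
1ldk	1lm8	0.73	0.82
1ldk	1r4m	0.60	0.78
1ldk	1z5s	0.61	0.50
1yov	1tt5	0.68	0.84
1yov	1jw9	0.80	0.68
1yov	1mn3	0.65	0.46
1yov	1fqv	0.63	0.65
1yov	2px9	0.78	0.68
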