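type,name,n_posts
1,epidemic overview release,1210
2,epidemic prevention and control measures,1362
3,science and disinformation,1739
4,epidemic line assistance stories,1952
5,epidemic impact,275
6,negative impact,74
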