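account_id,n_posts
Healthy Beijing,242
Healthy Guangdong,1174
Healthy Hubei,904
Healthy Hunan,70
Healthy Jiangsu,475
Healthy Shanghai,360
Healthy Sichuan official,771
Healthy Tianjin,1586
Healthy Zhejiang,543
Chongqing Health and hygiene,487
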