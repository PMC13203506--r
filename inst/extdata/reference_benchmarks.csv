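algorithm,mota,motp,idf1,idsw,fps
sort,68.00,82.00,65.00,127,120.2
kcf,72.00,84.00,70.00,98,55.7
deepsort,90.48,92.41,96.21,39,92.2
bytetrack,92.15,93.28,96.45,28,85.8
realtime,86.10,94.31,88.71,80,102.3
dual_locking,95.34,94.77,96.88,12,90.0
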