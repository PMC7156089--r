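table,group,initial_bin,c1,c2,c3,c4,c5,pct_printed
1,nonevents,1,36,12,0,2,0,28
1,nonevents,2,6,6,4,4,3,74
1,nonevents,3,3,3,1,5,3,93
1,nonevents,4,0,0,0,0,3,100
1,nonevents,5,0,0,0,0,0,NA
1,events,1,10,5,1,1,0,41
1,events,2,4,8,8,3,1,67
1,events,3,2,2,6,6,14,80
1,events,4,0,3,1,5,7,69
1,events,5,0,0,0,0,0,NA
2,nonevents,1,0,1,0,0,0,100
2,nonevents,2,5,8,2,0,0,47
2,nonevents,3,1,4,6,2,0,54
2,nonevents,4,0,2,2,4,1,56
2,nonevents,5,0,1,1,1,1,75
2,events,1,1,0,1,0,0,50
2,events,2,5,4,6,1,0,75
2,events,3,1,2,8,2,1,43
2,events,4,0,0,2,3,3,62
2,events,5,0,0,0,2,4,33
3,nonevents,1,45,3,0,0,0,6
3,nonevents,2,9,4,4,1,0,78
3,nonevents,3,3,9,6,5,0,74
3,nonevents,4,0,1,2,0,2,100
3,nonevents,5,0,0,0,2,1,67
3,events,1,23,6,3,1,0,30
3,events,2,4,6,4,0,0,57
3,events,3,0,1,4,4,9,78
3,events,4,0,0,2,8,15,68
3,events,5,0,0,0,0,9,0
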