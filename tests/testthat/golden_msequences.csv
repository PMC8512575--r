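order,taps,index,chip
3,3;2,0,1
3,3;2,1,1
3,3;2,2,1
3,3;2,3,-1
3,3;2,4,-1
3,3;2,5,1
3,3;2,6,-1
4,4;3,0,1
4,4;3,1,1
4,4;3,2,1
4,4;3,3,1
4,4;3,4,-1
4,4;3,5,-1
4,4;3,6,-1
4,4;3,7,1
4,4;3,8,-1
4,4;3,9,-1
4,4;3,10,1
4,4;3,11,1
4,4;3,12,-1
4,4;3,13,1
4,4;3,14,-1
5,5;3,0,1
5,5;3,1,1
5,5;3,2,1
5,5;3,3,1
5,5;3,4,1
5,5;3,5,-1
5,5;3,6,-1
5,5;3,7,-1
5,5;3,8,1
5,5;3,9,1
5,5;3,10,-1
5,5;3,11,1
5,5;3,12,1
5,5;3,13,1
5,5;3,14,-1
5,5;3,15,1
5,5;3,16,-1
5,5;3,17,1
5,5;3,18,-1
5,5;3,19,-1
5,5;3,20,-1
5,5;3,21,-1
5,5;3,22,1
5,5;3,23,-1
5,5;3,24,-1
5,5;3,25,1
5,5;3,26,-1
5,5;3,27,1
5,5;3,28,1
5,5;3,29,-1
5,5;3,30,-1
6,6;5,0,1
6,6;5,1,1
6,6;5,2,1
6,6;5,3,1
6,6;5,4,1
6,6;5,5,1
6,6;5,6,-1
6,6;5,7,-1
6,6;5,8,-1
6,6;5,9,-1
6,6;5,10,-1
6,6;5,11,1
6,6;5,12,-1
6,6;5,13,-1
6,6;5,14,-1
6,6;5,15,-1
6,6;5,16,1
6,6;5,17,1
6,6;5,18,-1
6,6;5,19,-1
6,6;5,20,-1
6,6;5,21,1
6,6;5,22,-1
6,6;5,23,1
6,6;5,24,-1
6,6;5,25,-1
6,6;5,26,1
6,6;5,27,1
6,6;5,28,1
6,6;5,29,1
6,6;5,30,-1
6,6;5,31,1
6,6;5,32,-1
6,6;5,33,-1
6,6;5,34,-1
6,6;5,35,1
6,6;5,36,1
6,6;5,37,1
6,6;5,38,-1
6,6;5,39,-1
6,6;5,40,1
6,6;5,41,-1
6,6;5,42,-1
6,6;5,43,1
6,6;5,44,-1
6,6;5,45,1
6,6;5,46,1
6,6;5,47,-1
6,6;5,48,1
6,6;5,49,1
6,6;5,50,1
6,6;5,51,-1
6,6;5,52,1
6,6;5,53,1
6,6;5,54,-1
6,6;5,55,-1
6,6;5,56,1
6,6;5,57,1
6,6;5,58,-1
6,6;5,59,1
6,6;5,60,-1
6,6;5,61,1
6,6;5,62,-1
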