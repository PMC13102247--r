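compound_id,ADT,iDock,LeDock,Qvina,Smina,Vina,PLANTS
IMPHY000749,31,29,17,28,23,28,24
IMPHY001112,12,18,19,18,19,17,22
IMPHY001137,29,28,32,28,31,27,32
IMPHY002235,20,31,30,31,30,31,31
IMPHY002354,23,21,25,20,25,21,21
IMPHY003213,9,5,11,6,4,6,15
IMPHY003388,5,2,1,2,1,2,4
IMPHY003529,7,17,13,17,14,19,14
IMPHY004244,11,24,21,24,24,24,27
IMPHY004515,15,7,14,8,8,7,12
IMPHY004657,18,16,16,15,18,16,23
IMPHY004740,4,26,4,26,20,30,3
IMPHY004834,6,10,3,11,5,10,1
IMPHY004879,21,30,8,30,28,29,19
IMPHY005033,16,9,9,11,7,9,8
IMPHY006072,10,25,15,25,27,25,18
IMPHY006688,17,20,25,18,21,18,26
IMPHY006882,26,3,22,3,9,3,25
IMPHY006927,28,12,23,11,17,12,10
IMPHY007665,19,10,12,11,10,13,13
IMPHY010091,30,8,29,7,15,8,29
IMPHY011624,14,27,28,26,29,26,20
IMPHY012536,3,6,5,4,6,4,5
IMPHY013006,27,22,31,22,22,23,16
IMPHY013015,25,13,20,8,13,14,11
IMPHY013285,8,19,10,20,12,20,6
IMPHY013601,13,15,24,15,16,11,17
IMPHY014026,32,32,6,32,32,32,30
IMPHY014076,1,13,6,8,3,15,7
IMPHY014146,22,4,18,5,11,5,9
IMPHY014498,2,1,2,1,2,1,2
IMPHY014981,23,23,27,22,26,22,28
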