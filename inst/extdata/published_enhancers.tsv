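gene	location	size_class
ken	2R:23868513..23869466	1kb
en	2R:11524814..11525958	1kb
aay	3L:9416225..9417230	1kb
mid	2L:5473726..5474732	1kb
5-HT2A	3R:4612279..4614294	2kb
trn	3L:13073977..13075024	1kb
hh	3R:23138154..23139164	1kb
Antp	3R:6948758..6949766	1kb
blot	3L:17409206..17410251	1kb
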