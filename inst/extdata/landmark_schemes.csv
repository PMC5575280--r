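species,point,definition
pulex,1,1st dorsal thorn (counting in anterior direction from spine)
pulex,2,2nd dorsal thorn
pulex,3,3rd dorsal thorn
pulex,4,4th dorsal thorn
pulex,5,5th dorsal thorn
pulex,6,Middle distance between spine and heart lower edge (point 7)
pulex,7,Heart lower edge horizontally projected on the dorsal edge
pulex,8,Head-carapace transition (dorsal bend)
pulex,9,Heart upper edge horizontally projected on the dorsal edge
pulex,10,Levator lower edge horizontally projected on the dorsal edge
pulex,11,Levator upper edge horizontally projected on the dorsal edge
pulex,12,2nd abductor lower edge horizontally projected on the dorsal edge
pulex,13,2nd abductor upper edge horizontally projected on the dorsal edge
pulex,14,1st abductor lower edge horizontally projected on the dorsal edge
pulex,15,1st abductor lower edge vertically projected on the dorsal edge
pulex,16,1st abductor upper edge vertically projected on the head outline
pulex,17,Crest of the head outline
pulex,18,Complex eye upper edge horizontally projected on the head outline
pulex,19,Complex eye centre horizontally projected on the head outline (ventral)
pulex,20,Complex eye lower edge horizontally projected on the head outline (ventral)
pulex,21,Rostrum tip
pulex,22,Head-carapace transition (ventral bend)
pulex,23,Heart upper edge horizontally projected on the ventral edge
pulex,24,Heart lower edge horizontally projected on the ventral edge
pulex,25,Horizontal projection of point 6 on the ventral edge
pulex,26,5th dorsal thorn horizontally projected on the ventral edge
pulex,27,4th dorsal thorn horizontally projected on the ventral edge
pulex,28,3rd dorsal thorn horizontally projected on the ventral edge
pulex,29,2nd dorsal thorn horizontally projected on the ventral edge
pulex,30,1st dorsal thorn horizontally projected on the ventral edge
pulex,31,Carapace lower edge ventrally
pulex,32,Transition carapace-spine (ventral bend)
pulex,33,Spine tip
longicephala,1,1st dorsal thorn (counting in anterior direction from spine)
longicephala,2,4th dorsal thorn
longicephala,3,7th dorsal thorn
longicephala,4,10th dorsal thorn
longicephala,5,13th dorsal thorn
longicephala,6,Middle distance between spine and heart lower edge (point 7)
longicephala,7,Heart lower edge horizontally projected on the dorsal edge
longicephala,8,Heart centre horizontally projected on the dorsal edge
longicephala,9,Heart upper edge horizontally projected on the dorsal edge
longicephala,10,Levator lower edge horizontally projected on the dorsal edge
longicephala,11,Levator upper edge horizontally projected on the dorsal edge
longicephala,12,2nd abductor lower edge horizontally projected on the dorsal edge
longicephala,13,2nd abductor upper edge horizontally projected on the dorsal edge
longicephala,14,Levator upper edge vertically projected on the head outline
longicephala,15,2nd abductor upper edge vertically projected on the head outline
longicephala,16,Caecum dorsal edge vertically projected on the head outline
longicephala,17,Complex eye ventral edge vertically projected on the head outline
longicephala,18,Complex eye lower edge horizontally projected on the head outline (ventral)
longicephala,19,Rostrum tip
longicephala,20,Complex eye ventral edge vertically projected on the rostrum edge (posterior)
longicephala,21,Head-carapace transition (ventral bend)
longicephala,22,Heart upper edge horizontally projected on the ventral edge
longicephala,23,Heart lower edge horizontally projected on the ventral edge
longicephala,24,Horizontal projection of point 6 on the ventral edge
longicephala,25,13th dorsal thorn horizontally projected on the ventral edge
longicephala,26,10th dorsal thorn horizontally projected on the ventral edge
longicephala,27,7th dorsal thorn horizontally projected on the ventral edge
longicephala,28,4th dorsal thorn horizontally projected on the ventral edge
longicephala,29,1st dorsal thorn horizontally projected on the ventral edge
longicephala,30,Transition carapace-spine (ventral bend)
longicephala,31,Spine tip
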