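Color,L,A,B,HueGroup,ClassOfCompounds,R,G,B
Dusk Slate,26.98291777,-2.775557562e-14,1.110223025e-14,purple-blue,melanin,0.25,0.25,0.25
Brick Red,45.79570524,50.93187627,28.57417963,red,azaphilones,0.75,0.25,0.25
Parrot Green,68.61881377,-59.14049432,52.29361662,green,,0.25,0.75,0.25
Citrine Yellow,75.35670206,-15.51573829,61.42801474,yellow,carotenoid,0.75,0.75,0.25
Gentian Blue,34.98663701,40.11001174,-66.76190129,blue,,0.25,0.25,0.75
Orchid Purple,50.12360527,65.69184633,-41.59164004,purple,naphthoquinone;polyketide,0.75,0.25,0.75
Verdigris,71.02338997,-33.87290866,-10.18297964,blue-green,xylindein,0.25,0.75,0.75
Pearl Plumbeous,77.43137189,0,0,purple-blue,,0.75,0.75,0.75
Abyss Teal,25,-50,-50,blue-green,xylindein,0,0.3090091263,0.5319456332
Glacier Cyan,75,-50,-50,blue-green,xylindein,0,0.8324819761,1
Midnight Violet,25,50,-50,purple-blue,naphthoquinone,0.3492053605,0.07753680078,0.5359919175
Light Phlox,75,50,-50,purple,naphthoquinone,0.9003539635,0.599821893,1
Calliste Deep,25,-50,50,green,,0,0.288420601,0
Meadow Chartreuse,75,-50,50,green-yellow,carotenoid,0.4401091451,0.8078226689,0.3392940012
Mars Umber,25,50,50,yellow-red,melanin,0.5081836719,0,0
Apricot Buff,75,50,50,yellow-red,carotenoid,1,0.5612313013,0.3716497307
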