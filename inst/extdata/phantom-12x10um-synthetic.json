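{"version":1,"seed":12,"slab":{"y":200,"z":200,"x":200},"n_surround":1,"fill":0.0942477796076938,"cylinders":[{"cy":79.1033880205019,"cz":-47.7470128952067,"r":10,"n":1.6285},{"cy":72.8710271003383,"cz":63.3898248129208,"r":10,"n":1.6285},{"cy":-37.0576788300786,"cz":-64.9211387874495,"r":10,"n":1.6285},{"cy":45.0945734029144,"cz":-32.9342451695214,"r":10,"n":1.6285},{"cy":-64.7907365672867,"cz":78.3579493204511,"r":10,"n":1.6285},{"cy":31.793916726301,"cz":22.7943798130753,"r":10,"n":1.6285},{"cy":-77.9376586059208,"cz":18.0596752590028,"r":10,"n":1.6285},{"cy":10.9249893099775,"cz":51.0329939835926,"r":10,"n":1.6285},{"cy":-25.0289836507527,"cz":-14.3557781853837,"r":10,"n":1.6285},{"cy":-3.04374759910569,"cz":-7.09827200185416,"r":10,"n":1.6285},{"cy":15.283022013988,"cz":-20.8511569072609,"r":10,"n":1.6285},{"cy":55.9814196886984,"cz":39.3531895946512,"r":10,"n":1.6285}]}
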