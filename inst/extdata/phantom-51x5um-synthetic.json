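{"version":1,"seed":51,"slab":{"y":200,"z":200,"x":200},"n_surround":1,"fill":0.100138265833175,"cylinders":[{"cy":-35.2513182388504,"cz":45.6923462266258,"r":5,"n":1.6285},{"cy":30.2744230654041,"cz":5.12027399995777,"r":5,"n":1.6285},{"cy":74.9507977653958,"cz":-64.1665334121877,"r":5,"n":1.6285},{"cy":79.8873076548617,"cz":-82.7838219870654,"r":5,"n":1.6285},{"cy":94.3487709478189,"cz":17.879843387137,"r":5,"n":1.6285},{"cy":35.3025929510451,"cz":69.0813415113647,"r":5,"n":1.6285},{"cy":0.844724009301471,"cz":-18.8016657059139,"r":5,"n":1.6285},{"cy":-57.2248649505467,"cz":-70.8511575042835,"r":5,"n":1.6285},{"cy":-17.3540732775389,"cz":86.3321921249099,"r":5,"n":1.6285},{"cy":59.8503726456632,"cz":-24.1293586709296,"r":5,"n":1.6285},{"cy":10.3188795462155,"cz":7.23261466626514,"r":5,"n":1.6285},{"cy":27.3208699915362,"cz":20.1310204686649,"r":5,"n":1.6285},{"cy":-22.8651499859015,"cz":-29.6354179125367,"r":5,"n":1.6285},{"cy":78.7799762105794,"cz":5.04621898561192,"r":5,"n":1.6285},{"cy":27.3152339107629,"cz":32.1910352591047,"r":5,"n":1.6285},{"cy":-84.5283327175942,"cz":-17.049472523464,"r":5,"n":1.6285},{"cy":48.8462878172746,"cz":51.7725261891484,"r":5,"n":1.6285},{"cy":39.0102657249693,"cz":-93.5362841438616,"r":5,"n":1.6285},{"cy":-2.68264029702315,"cz":58.181811534743,"r":5,"n":1.6285},{"cy":-10.5684618250181,"cz":-23.9186550801897,"r":5,"n":1.6285},{"cy":41.804058926669,"cz":-6.25563269823148,"r":5,"n":1.6285},{"cy":-64.3030994319329,"cz":58.4134618136746,"r":5,"n":1.6285},{"cy":-85.8094425363261,"cz":-43.1678664951108,"r":5,"n":1.6285},{"cy":-66.4056834947464,"cz":25.3944781652825,"r":5,"n":1.6285},{"cy":-1.0756162130681,"cz":-60.4241580571729,"r":5,"n":1.6285},{"cy":46.3025141884599,"cz":-41.3421099981767,"r":5,"n":1.6285},{"cy":-65.9262911308263,"cz":-4.4947681778834,"r":5,"n":1.6285},{"cy":-60.3994662916282,"cz":-44.5683175857495,"r":5,"n":1.6285},{"cy":-42.9158273173387,"cz":-82.7237089885724,"r":5,"n":1.6285},{"cy":-23.7899301439858,"cz":-47.633457407661,"r":5,"n":1.6285},{"cy":93.184516596258,"cz":80.2706721240677,"r":5,"n":1.6285},{"cy":69.6745836988937,"cz":82.6450760663587,"r":5,"n":1.6285},{"cy":55.5682595050637,"cz":29.0831033428447,"r":5,"n":1.6285},{"cy":-49.3049680694712,"cz":51.6949962046053,"r":5,"n":1.6285},{"cy":13.1222847922408,"cz":25.191598560831,"r":5,"n":1.6285},{"cy":-13.6120606525213,"cz":-91.5443826519237,"r":5,"n":1.6285},{"cy":-72.9741532670812,"cz":73.8010972399313,"r":5,"n":1.6285},{"cy":47.4218620982693,"cz":39.6737108297936,"r":5,"n":1.6285},{"cy":20.7303523154231,"cz":-69.6798571340587,"r":5,"n":1.6285},{"cy":45.6847504241021,"cz":-72.1024018651629,"r":5,"n":1.6285},{"cy":24.974587207575,"cz":50.8317461511479,"r":5,"n":1.6285},{"cy":49.5635525374124,"cz":68.491000816428,"r":5,"n":1.6285},{"cy":-3.59349092101738,"cz":38.4710738626773,"r":5,"n":1.6285},{"cy":65.7339382614611,"cz":72.4555626269067,"r":5,"n":1.6285},{"cy":-25.8614529818144,"cz":12.2390382780588,"r":5,"n":1.6285},{"cy":-35.4624966652339,"cz":-33.0992661770898,"r":5,"n":1.6285},{"cy":-22.838838933308,"cz":-16.7910872317703,"r":5,"n":1.6285},{"cy":85.9461793093534,"cz":-3.09103243678864,"r":5,"n":1.6285},{"cy":-71.9576710372709,"cz":39.2524191724694,"r":5,"n":1.6285},{"cy":4.77944140160361,"cz":-80.8750329289332,"r":5,"n":1.6285},{"cy":60.282522759286,"cz":8.8886108621234,"r":5,"n":1.6285}]}
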