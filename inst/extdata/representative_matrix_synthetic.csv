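"cell_id","frame_index","delta_n","delta_t"
"S2cell",0,0,0
"S2cell",1,0,0
"S2cell",2,0,0
"S2cell",3,1,0
"S2cell",4,0,0
"S2cell",5,0,0
"S2cell",6,0,0
"S2cell",7,0,0
"S2cell",8,0,0
"S2cell",9,-1,0
"S2cell",10,0,0
"S2cell",11,0,0
"S2cell",12,0,0
"S2cell",13,1,0
"S2cell",14,0,0
"S2cell",15,0,0
"S2cell",16,0,0
"S2cell",17,0,0
"S2cell",18,0,0
"S2cell",19,-1,0
"S2cell",20,0,0
"S2cell",21,0,0
"S2cell",22,1,0
"S2cell",23,0,0
"S2cell",24,0,0
"S2cell",25,0,0
"S2cell",26,0,0
"S2cell",27,0,0
"S2cell",28,-1,0
"S2cell",29,0,0
"S2cell",30,0,0
"S2cell",31,1,0
"S2cell",32,0,0
"S2cell",33,0,0
"S2cell",34,0,0
"S2cell",35,0,0
"S2cell",36,0,0
"S2cell",37,-1,0
"S2cell",38,0,0
"S2cell",39,0,0
"S2cell",40,1,0
"S2cell",41,0,0
"S2cell",42,0,0
"S2cell",43,0,0
"S2cell",44,0,0
"S2cell",45,0,0
"S2cell",46,-1,0
"S2cell",47,0,0
"S2cell",48,0,0
"S2cell",49,1,0
"S2cell",50,0,0
"S2cell",51,0,0
"S2cell",52,0,0
"S2cell",53,0,0
"S2cell",54,0,0
"S2cell",55,-1,0
"S2cell",56,0,0
"S2cell",57,0,0
"S2cell",58,1,0
"S2cell",59,0,0
"S2cell",60,0,0
"S2cell",61,0,0
"S2cell",62,0,0
"S2cell",63,0,0
"S2cell",64,0,0
"S2cell",65,0,0
"S2cell",66,0,1
"S2cell",67,0,0
"S2cell",68,0,0
"S2cell",69,0,0
"S2cell",70,0,0
"S2cell",71,0,0
"S2cell",72,-1,0
"S2cell",73,0,0
"S2cell",74,0,0
"S2cell",75,1,0
"S2cell",76,0,0
"S2cell",77,0,0
"S2cell",78,0,0
"S2cell",79,0,0
"S2cell",80,0,0
"S2cell",81,-1,0
"S2cell",82,0,0
"S2cell",83,0,0
"S2cell",84,1,0
"S2cell",85,0,0
"S2cell",86,0,0
"S2cell",87,0,0
"S2cell",88,0,0
"S2cell",89,0,0
"S2cell",90,-1,0
"S2cell",91,0,0
"S2cell",92,0,0
"S2cell",93,1,0
"S2cell",94,0,0
"S2cell",95,0,0
"S2cell",96,0,0
"S2cell",97,0,0
"S2cell",98,0,0
"S2cell",99,-1,0
"S2cell",100,0,0
"S2cell",101,1,0
"S2cell",102,0,0
"S2cell",103,0,0
"S2cell",104,0,0
"S2cell",105,0,0
"S2cell",106,0,0
"S2cell",107,-1,0
"S2cell",108,0,0
"S2cell",109,0,0
"S2cell",110,1,0
"S2cell",111,0,0
"S2cell",112,0,0
"S2cell",113,0,0
"S2cell",114,0,0
"S2cell",115,0,0
"S2cell",116,-1,0
"S2cell",117,0,0
"S2cell",118,0,0
"S2cell",119,1,0
"S2cell",120,0,0
"S2cell",121,0,0
"S2cell",122,0,0
"S2cell",123,0,0
"S2cell",124,0,0
"S2cell",125,0,0
"S2cell",126,0,0
"S2cell",127,0,0
"S2cell",128,0,0
"S2cell",129,1,0
"S2cell",130,-1,0
"S2cell",131,0,0
"S2cell",132,0,0
"S2cell",133,0,0
"S2cell",134,0,0
"S2cell",135,-1,0
"S2cell",136,0,0
"S2cell",137,0,0
"S2cell",138,1,0
"S2cell",139,0,0
"S2cell",140,0,0
"S2cell",141,0,0
"S2cell",142,0,0
"S2cell",143,0,0
"S2cell",144,-1,0
"S2cell",145,0,0
"S2cell",146,0,0
"S2cell",147,1,0
"S2cell",148,0,0
"S2cell",149,0,0
"S2cell",150,0,0
"S2cell",151,0,0
"S2cell",152,0,0
"S2cell",153,-1,0
"S2cell",154,0,0
"S2cell",155,0,0
"S2cell",156,0,0
"S2cell",157,1,0
"S2cell",158,0,0
"S2cell",159,0,0
"S2cell",160,0,0
"S2cell",161,0,0
"S2cell",162,0,0
"S2cell",163,-1,0
"S2cell",164,0,0
"S2cell",165,0,0
"S2cell",166,1,0
"S2cell",167,0,0
"S2cell",168,0,0
"S2cell",169,0,0
"S2cell",170,0,0
"S2cell",171,0,0
"S2cell",172,-1,0
"S2cell",173,0,0
"S2cell",174,0,0
"S2cell",175,0,0
"S2cell",176,0,0
"S2cell",177,1,0
"S2cell",178,0,0
"S2cell",179,0,0
"S2cell",180,0,0
"S2cell",181,0,0
"S2cell",182,0,0
"S2cell",183,-1,0
"S2cell",184,0,0
"S2cell",185,0,0
"S2cell",186,0,0
"S2cell",187,0,0
"S2cell",188,0,0
"S2cell",189,1,0
"S2cell",190,0,0
"S2cell",191,0,0
"S2cell",192,0,0
"S2cell",193,0,0
"S2cell",194,0,0
"S2cell",195,-1,0
"S2cell",196,0,0
"S2cell",197,0,0
"S2cell",198,0,0
"S2cell",199,0,0
"S2cell",200,0,0
"S2cell",201,0,0
"S2cell",202,0,0
"S2cell",203,1,0
"S2cell",204,0,0
"S2cell",205,0,0
"S2cell",206,0,0
"S2cell",207,0,0
"S2cell",208,0,0
"S2cell",209,-1,0
"S2cell",210,0,0
"S2cell",211,0,0
"S2cell",212,0,0
"S2cell",213,0,0
"S2cell",214,0,0
"S2cell",215,0,0
"S2cell",216,0,0
"S2cell",217,0,0
"S2cell",218,0,0
"S2cell",219,1,0
"S2cell",220,0,0
"S2cell",221,0,0
"S2cell",222,0,0
"S2cell",223,0,0
"S2cell",224,0,0
"S2cell",225,-1,0
"S2cell",226,0,0
"S2cell",227,0,0
"S2cell",228,0,0
"S2cell",229,0,0
"S2cell",230,0,0
"S2cell",231,0,0
"S2cell",232,0,0
"S2cell",233,0,0
"S2cell",234,0,0
"S2cell",235,0,0
"S2cell",236,0,0
"S2cell",237,0,0
"S2cell",238,0,0
"S2cell",239,0,0
"S2cell",240,0,0
"S2cell",241,0,0
"S2cell",242,0,0
"S2cell",243,0,0
"S2cell",244,0,0
"S2cell",245,0,0
"S2cell",246,0,0
"S2cell",247,0,0
"S2cell",248,0,0
"S2cell",249,0,0
"S2cell",250,0,0
"S2cell",251,0,0
"S2cell",252,0,0
"S2cell",253,0,0
"S2cell",254,0,0
"S2cell",255,0,0
"S2cell",256,0,0
"S2cell",257,0,0
"S2cell",258,0,0
"S2cell",259,0,0
"S2cell",260,0,0
"S2cell",261,0,0
"S2cell",262,0,0
"S2cell",263,0,0
"S2cell",264,0,0
"S2cell",265,0,0
"S2cell",266,0,0
"S2cell",267,0,0
"S2cell",268,0,0
"S2cell",269,0,0
"S2cell",270,0,0
"S2cell",271,0,0
"S2cell",272,0,0
"S2cell",273,0,0
"S2cell",274,0,0
"S2cell",275,0,0
"S2cell",276,0,0
"S2cell",277,0,0
"S2cell",278,0,0
"S2cell",279,0,0
"S2cell",280,0,0
"S2cell",281,0,0
"S2cell",282,0,0
"S2cell",283,0,0
"S2cell",284,0,0
"S2cell",285,0,0
"S2cell",286,0,0
"S2cell",287,0,0
"S2cell",288,0,0
"S2cell",289,0,0
"S2cell",290,0,0
"S2cell",291,0,0
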