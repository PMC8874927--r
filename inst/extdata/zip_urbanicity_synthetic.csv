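zip,class
30001,urban
30002,urban
30003,urban
30004,urban
30005,urban
30006,urban
30007,urban
30008,urban
30009,urban
30010,urban
30011,urban
30012,urban
30013,urban
30014,urban
30015,urban
30016,urban
30017,urban
30018,urban
30019,urban
30020,urban
30021,urban
30022,urban
30023,urban
30024,urban
30025,urban
30026,urban
30027,urban
30028,urban
30029,urban
30030,urban
30031,suburban
30032,suburban
30033,suburban
30034,suburban
30035,suburban
30036,suburban
30037,suburban
30038,suburban
30039,suburban
30040,suburban
30041,suburban
30042,suburban
30043,suburban
30044,suburban
30045,suburban
30046,suburban
30047,suburban
30048,suburban
30049,suburban
30050,suburban
30051,suburban
30052,suburban
30053,suburban
30054,suburban
30055,suburban
30056,suburban
30057,suburban
30058,suburban
30059,suburban
30060,suburban
30061,rural
30062,rural
30063,rural
30064,rural
30065,rural
30066,rural
30067,rural
30068,rural
30069,rural
30070,rural
30071,rural
30072,rural
30073,rural
30074,rural
30075,rural
30076,rural
30077,rural
30078,rural
30079,rural
30080,rural
30081,rural
30082,rural
30083,rural
30084,rural
30085,rural
30086,rural
30087,rural
30088,rural
30089,rural
30090,rural
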