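farm_id,category
IF001,abandon
IF002,abandon
IF003,abandon
IF004,abandon
IF005,abandon
IF006,abandon
IF007,abandon
IF008,abandon
IF009,abandon
IF010,abandon
IF011,abandon
IF012,abandon
IF013,abandon
IF014,abandon
IF015,abandon
IF016,abandon
IF017,abandon
IF018,abandon
IF019,abandon
IF020,abandon
IF021,abandon
IF022,abandon
IF023,abandon
IF024,abandon
IF025,abandon
IF026,abandon
IF027,abandon
IF028,abandon
IF029,abandon
IF030,abandon
IF031,abandon
IF032,abandon
IF033,abandon
IF034,abandon
IF035,abandon
IF036,abandon
IF037,abandon
IF038,abandon
IF039,abandon
IF040,abandon
IF041,abandon
IF042,abandon
IF043,abandon
IF044,abandon
IF045,abandon
IF046,abandon
IF047,abandon
IF048,abandon
IF049,abandon
IF050,abandon
IF051,abandon
IF052,abandon
IF053,abandon
IF054,abandon
IF055,abandon
IF056,abandon
IF057,abandon
IF058,dump
IF059,dump
IF060,dump
IF061,dump
IF062,dump
IF063,dump
IF064,dump
IF065,dump
IF066,feeding_station
IF067,feeding_station
IF068,feeding_station
IF069,collection_service
IF070,collection_service
IF071,collection_service
IF072,collection_service
IF073,collection_service
IF074,collection_service
IF075,collection_service
IF076,collection_service
IF077,collection_service
IF078,collection_service
IF079,collection_service
IF080,collection_service
IF081,collection_service
IF082,collection_service
IF083,collection_service
IF084,collection_service
IF085,collection_service
IF086,collection_service
IF087,collection_service
IF088,collection_service
IF089,collection_service
IF090,buried
IF091,buried
IF092,mortuary
IF093,never
IF094,never
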