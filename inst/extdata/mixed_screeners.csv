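record_id,form,linked_screener_id,client_timestamp,server_timestamp,submit_instant,completion_minutes,counties_marked,zip,heard_source,captcha_passed,honeypot_value,email,phone,postal_address,ip_hash,child_age_years,child_grade,sb_weak,sb_attention,open_text
S00001,screener,,2022-01-27T12:06:52+0000,2022-01-27T12:06:52+0000,2022-01-27T12:06:52+0000,2.101,County19,20694,community_flyer,TRUE,,martha.mason85@mailbox.net,410-335-7114,101 Lake St,h373a1bcc,5,0,the man,strongly agree,
S00002,screener,,2022-01-27T13:07:54+0000,2022-01-27T13:07:54+0000,2022-01-27T13:07:54+0000,2.913,County19,20691,facebook_ad,TRUE,,judy.evans75@mailbox.net,410-942-1757,102 Walnut St,h35bb91b6,14,7,the man,strongly agree,
S00003,screener,,2022-01-27T13:52:32+0000,2022-01-27T13:52:32+0000,2022-01-27T13:52:32+0000,2.884,County23,20715,community_flyer,TRUE,,sharon.cook45@example.org,410-853-5363,103 Park St,h5b95d656,15,8,the man,strongly agree,
S00004,screener,,2022-01-27T14:41:39+0000,2022-01-27T14:41:39+0000,2022-01-27T14:41:39+0000,2.409,County23,20714,facebook_ad,TRUE,,daniel.davis28@mailbox.net,410-460-2139,104 Park St,h3f18bead,11,6,the man,strongly agree,
S00005,screener,,2022-01-27T15:13:55+0000,2022-01-27T15:13:55+0000,2022-01-27T15:13:55+0000,2.152,County03,20611,postcard,TRUE,,brenda.carter49@mailbox.net,410-017-5451,105 Elm St,h3601f364,14,8,the man,strongly agree,
S00006,screener,,2022-01-27T15:42:47+0000,2022-01-27T15:42:47+0000,2022-01-27T15:42:47+0000,2.82,County02,20608,community_flyer,TRUE,,lisa.ward38@mailbox.net,410-315-5104,106 Lake St,h6baa1ac6,8,1,the man,strongly agree,
S00007,screener,,2022-01-27T16:03:27+0000,2022-01-27T16:03:27+0000,2022-01-27T16:03:27+0000,1.65,County19,20695,community_flyer,TRUE,,sean.holmes32@example.org,410-116-7987,107 River St,h6325cf94,14,8,the man,strongly agree,
S00008,screener,,2022-01-27T16:14:52+0000,2022-01-27T16:14:52+0000,2022-01-27T16:14:52+0000,2.458,County08,20638,community_flyer,TRUE,,gregory.bailey27@mailbox.net,410-696-6658,108 Walnut St,h389cc569,8,1,the man,strongly agree,
S00009,screener,,2022-01-27T16:46:29+0000,2022-01-27T16:46:29+0000,2022-01-27T16:46:29+0000,1.413,County07,20632,postcard,TRUE,,sarah.ford90@example.org,410-822-1399,109 Hill St,h23d780e5,13,7,the man,strongly agree,
S00010,screener,,2022-01-27T16:59:24+0000,2022-01-27T16:59:24+0000,2022-01-27T16:59:24+0000,2.736,County15,20674,listserv,TRUE,,julia.cook91@inbox.co,410-237-5366,110 Sunset St,h09795be0,9,2,the man,strongly agree,
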