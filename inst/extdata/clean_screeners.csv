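record_id,form,linked_screener_id,client_timestamp,server_timestamp,submit_instant,completion_minutes,counties_marked,zip,heard_source,captcha_passed,honeypot_value,email,phone,postal_address,ip_hash,child_age_years,child_grade,sb_weak,sb_attention,open_text
S00001,screener,,2022-01-27T12:28:09+0000,2022-01-27T12:28:09+0000,2022-01-27T12:28:09+0000,1.799,County03,20612,postcard,TRUE,,ruth.fox91@mailbox.net,410-954-3276,101 Park St,h504dd20e,10,3,the man,strongly agree,
S00002,screener,,2022-01-27T12:40:03+0000,2022-01-27T12:40:03+0000,2022-01-27T12:40:03+0000,2.351,County23,20711,listserv,TRUE,,maria.holmes02@inbox.co,410-598-6500,102 Walnut St,h4e9b2f7a,8,2,the man,strongly agree,
S00003,screener,,2022-01-27T13:19:33+0000,2022-01-27T13:19:33+0000,2022-01-27T13:19:33+0000,1.961,County10,20650,community_flyer,TRUE,,martha.dale57@inbox.co,410-024-8033,103 Main St,h0c603ee5,10,5,the man,strongly agree,
S00004,screener,,2022-01-27T13:56:46+0000,2022-01-27T13:56:46+0000,2022-01-27T13:56:46+0000,2.068,County23,20712,facebook_ad,TRUE,,alexander.davis96@mailbox.net,410-643-3751,104 Main St,h59e228b6,11,4,the man,strongly agree,
S00005,screener,,2022-01-27T14:25:52+0000,2022-01-27T14:25:52+0000,2022-01-27T14:25:52+0000,1.634,County08,20640,postcard,TRUE,,rebecca.bailey41@mailbox.net,410-744-2693,105 Park St,h4dd9047f,8,1,the man,strongly agree,
S00006,screener,,2022-01-27T15:11:25+0000,2022-01-27T15:11:25+0000,2022-01-27T15:11:25+0000,2.63,County15,20671,community_flyer,TRUE,,edward.kemp23@mailbox.net,410-872-8705,106 Maple St,h7f1ecded,12,6,the man,strongly agree,
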