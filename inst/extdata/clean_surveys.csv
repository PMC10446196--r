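record_id,form,linked_screener_id,client_timestamp,server_timestamp,submit_instant,completion_minutes,counties_marked,zip,heard_source,captcha_passed,honeypot_value,email,phone,postal_address,ip_hash,child_age_years,child_grade,sb_weak,sb_attention,open_text,item_01,item_02,item_03,item_04,item_05,item_06,item_07,item_08,item_09,item_10,item_11,item_12,item_13,item_14,item_15,item_16,item_17,item_18,item_19,item_20,item_dupcheck,item_dupcheck_rep
R00001,survey,S00001,2022-01-27T12:44:43+0000,2022-01-27T12:44:43+0000,2022-01-27T12:44:43+0000,14.558,County03,20612,postcard,TRUE,,ruth.fox91@mailbox.net,410-954-3276,101 Park St,h504dd20e,10,3,the man,strongly agree,tutoring improved recess district transport county art neighbors school,b,a,a,a,a,a,d,b,c,a,c,c,a,b,a,b,b,a,b,d,no,no
R00002,survey,S00002,2022-01-27T12:54:31+0000,2022-01-27T12:54:31+0000,2022-01-27T12:54:31+0000,12.472,County23,20711,listserv,TRUE,,maria.holmes02@inbox.co,410-598-6500,102 Walnut St,h4e9b2f7a,8,2,the man,strongly agree,recess planning ventilation teacher hybrid community children transport schedule,b,c,d,d,d,b,a,b,d,d,a,b,c,d,c,c,a,b,b,c,no,no
R00003,survey,S00003,2022-01-27T13:34:38+0000,2022-01-27T13:34:38+0000,2022-01-27T13:34:38+0000,13.078,County10,20650,community_flyer,TRUE,,martha.dale57@inbox.co,410-024-8033,103 Main St,h0c603ee5,10,5,the man,strongly agree,flexibility virtual projects family cleaning library afternoons math parents,b,d,d,a,b,a,d,c,d,a,b,a,d,a,c,b,d,c,b,b,no,no
R00004,survey,S00004,2022-01-27T14:17:31+0000,2022-01-27T14:17:31+0000,2022-01-27T14:17:31+0000,18.764,County23,20712,facebook_ad,TRUE,,alexander.davis96@mailbox.net,410-643-3751,104 Main St,h59e228b6,11,4,the man,strongly agree,helpful improved activities children breakfast ventilation pickup neighbors stress,d,a,a,d,b,b,a,a,b,a,d,a,b,c,d,d,a,b,c,b,no,no
R00005,survey,S00005,2022-01-27T14:46:04+0000,2022-01-27T14:46:04+0000,2022-01-27T14:46:04+0000,18.206,County08,20640,postcard,TRUE,,rebecca.bailey41@mailbox.net,410-744-2693,105 Park St,h4dd9047f,8,1,the man,strongly agree,communication sports buses improved mornings difficult dropoff counselors cleaning,a,b,c,d,b,d,d,a,d,a,d,b,c,a,a,c,d,b,b,c,yes,yes
R00006,survey,S00006,2022-01-27T15:29:47+0000,2022-01-27T15:29:47+0000,2022-01-27T15:29:47+0000,16.363,County15,20671,community_flyer,TRUE,,edward.kemp23@mailbox.net,410-872-8705,106 Maple St,h7f1ecded,12,6,the man,strongly agree,stress resources activities flexibility lunch art testing ventilation friends,a,a,c,b,d,c,c,b,a,b,a,a,b,a,b,c,b,d,d,d,yes,yes
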