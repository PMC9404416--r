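animal_id,herd,birth_date,sire,dam,event_type,event_date,event_value
CW001,H1,2000-01-10,SR01,DM01,SERVICE,2001-06-05,failure
CW001,H1,2000-01-10,SR01,DM01,SERVICE,2001-06-26,success
CW001,H1,2000-01-10,SR01,DM01,DIAGNOSIS,2001-08-07,pregnant
CW001,H1,2000-01-10,SR01,DM01,CALVING,2002-04-02,1
CW001,H1,2000-01-10,SR01,DM01,SERVICE,2002-06-28,success
CW001,H1,2000-01-10,SR01,DM01,DIAGNOSIS,2002-08-09,pregnant
CW001,H1,2000-01-10,SR01,DM01,CALVING,2003-04-04,2
CW002,H1,2000-02-20,SR01,DM02,SERVICE,2001-07-14,success
CW002,H1,2000-02-20,SR01,DM02,DIAGNOSIS,2001-08-25,pregnant
CW002,H1,2000-02-20,SR01,DM02,CALVING,2002-04-20,1
CW002,H1,2000-02-20,SR01,DM02,SERVICE,2002-07-19,failure
CW002,H1,2000-02-20,SR01,DM02,SERVICE,2002-08-09,failure
CW002,H1,2000-02-20,SR01,DM02,SERVICE,2002-08-30,success
CW002,H1,2000-02-20,SR01,DM02,DIAGNOSIS,2002-10-11,pregnant
CW002,H1,2000-02-20,SR01,DM02,CALVING,2003-06-06,2
CW003,H2,2000-03-05,0,DM03,SERVICE,2001-08-01,failure
CW003,H2,2000-03-05,0,DM03,SERVICE,2001-08-22,success
CW003,H2,2000-03-05,0,DM03,DIAGNOSIS,2001-10-03,pregnant
CW003,H2,2000-03-05,0,DM03,CALVING,2002-05-29,1
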