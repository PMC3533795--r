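plate_id,compound_id,concentration_uM,channel,replicate,role,fluorescence
P1,tamoxifen_like,2.5,lipidtox,1,test,30020
P1,tamoxifen_like,2.5,lipidtox,2,test,29660
P1,tamoxifen_like,2.5,lipidtox,3,test,30400
P1,tamoxifen_like,2.5,lipidtox,4,test,29850
P1,tamoxifen_like,5.0,lipidtox,1,test,36300
P1,tamoxifen_like,5.0,lipidtox,2,test,36700
P1,tamoxifen_like,5.0,lipidtox,3,test,35900
P1,tamoxifen_like,5.0,lipidtox,4,test,36100
P1,loperamide_like,2.5,lipidtox,1,test,5030
P1,loperamide_like,2.5,lipidtox,2,test,4760
P1,loperamide_like,2.5,lipidtox,3,test,4450
P1,loperamide_like,2.5,lipidtox,4,test,4920
P1,loperamide_like,5.0,lipidtox,1,test,8510
P1,loperamide_like,5.0,lipidtox,2,test,8090
P1,loperamide_like,5.0,lipidtox,3,test,8440
P1,loperamide_like,5.0,lipidtox,4,test,8260
P1,tamoxifen_like,2.5,dapi,1,test,19800
P1,tamoxifen_like,2.5,dapi,2,test,20400
P1,tamoxifen_like,2.5,dapi,3,test,19100
P1,tamoxifen_like,2.5,dapi,4,test,20100
P1,tamoxifen_like,5.0,dapi,1,test,18600
P1,tamoxifen_like,5.0,dapi,2,test,19400
P1,tamoxifen_like,5.0,dapi,3,test,18900
P1,tamoxifen_like,5.0,dapi,4,test,19700
P1,loperamide_like,2.5,dapi,1,test,20600
P1,loperamide_like,2.5,dapi,2,test,19900
P1,loperamide_like,2.5,dapi,3,test,20900
P1,loperamide_like,2.5,dapi,4,test,20300
P1,loperamide_like,5.0,dapi,1,test,19500
P1,loperamide_like,5.0,dapi,2,test,20200
P1,loperamide_like,5.0,dapi,3,test,19800
P1,loperamide_like,5.0,dapi,4,test,20700
P1,CTRL,0,lipidtox,1,control,4490
P1,CTRL,0,lipidtox,2,control,4610
P1,CTRL,0,lipidtox,3,control,4390
P1,CTRL,0,lipidtox,4,control,4530
P1,CTRL,0,lipidtox,5,control,4570
P1,CTRL,0,lipidtox,6,control,4450
P1,CTRL,0,lipidtox,7,control,4480
P1,CTRL,0,lipidtox,8,control,4510
P1,BG,0,lipidtox,1,background,410
P1,BG,0,lipidtox,2,background,390
P1,BG,0,lipidtox,3,background,405
P1,BG,0,lipidtox,4,background,398
P1,CTRL,0,dapi,1,control,20100
P1,CTRL,0,dapi,2,control,19800
P1,CTRL,0,dapi,3,control,20400
P1,CTRL,0,dapi,4,control,19900
P1,CTRL,0,dapi,5,control,20250
P1,CTRL,0,dapi,6,control,20050
P1,CTRL,0,dapi,7,control,19700
P1,CTRL,0,dapi,8,control,20200
P1,BG,0,dapi,1,background,510
P1,BG,0,dapi,2,background,480
P1,BG,0,dapi,3,background,495
P1,BG,0,dapi,4,background,505
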